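# bearbehave

Behaviour classification and activity budgets from brown bear
accelerometry.

Hunted animals can respond to the risk humans pose without ever being shot:
they shift *when* they are active. Measuring that requires knowing what a
collared animal is doing every few seconds, around the clock. `bearbehave`
implements the full analysis chain for Scandinavian brown bears (*Ursus
arctos*) carrying 8 Hz tri-axial accelerometers: raw acceleration streams
are cut into 3 s windows, summarised into 36 signal features, classified
into four behaviours (resting, feeding, walking, running) with a random
forest trained on video-annotated captive-bear data, and converted into the
response variables of a hunting-risk analysis — running bouts per day, the
proportion of bouts started inside legal hunting hours, diel activity
profiles and daily GPS distance, stratified by the pre-hunting (August
1–20) and hunting (August 21–31) periods.

It is intended for movement ecologists working with collar accelerometry
who need a tested, reproducible version of this pipeline, and it ships a
synthetic-data module that generates collar-like accelerometry, annotation
events and GPS tracks with known behavioural ground truth, so every stage
can be exercised end to end without access to field data.

## The model in brief

For each axis the **static** (postural/gravitational) acceleration is a 3 s
running mean of the raw signal; **dynamic body acceleration** is the
remainder, `DBA = raw − static`, and the **overall dynamic body
acceleration** per sample is

```
ODBA = |DBA_x| + |DBA_y| + |DBA_z|
```

with the **magnitude** `sqrt(x² + y² + z²)`. Every complete 3 s window (24
samples at 8 Hz) is summarised into 36 features: mean, SD, max, min,
kurtosis and skewness of each axis and of the magnitude; pairwise axis
correlations; mean DBA per axis; total and mean ODBA; and the dominant
power spectral density of each axis and the magnitude (maximum of the
mean-removed periodogram). A random forest (1000 trees, `mtry` tuned by
out-of-bag error) maps feature vectors to behaviours. Performance is
summarised per class by precision `TP/(TP+FP)`, recall `TP/(TP+FN)` and the
Matthews correlation coefficient

```
MCC = (TP·TN − FP·FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))
```

which is robust to the strong class imbalance (running is rare). Downstream,
walking and feeding predictions are pooled into a *feedwalking* state,
running bouts are maximal runs of consecutive running windows, and a bout
falls inside legal hunting hours when it starts between one hour before
local sunrise and two hours before local sunset (NOAA solar geometry at
61° N, 15° E, UTC+2).

## Worked example

Simulate a captive observation day, train the classifier on the ground
truth, then evaluate a fresh day and derive the activity budget:

```r
library(bearbehave)

sched <- simulate_schedule(6 * 3600, seed = 42)   # behaviour schedule
acc   <- simulate_accel(sched, seed = 43)         # 8 Hz tri-axial stream
train <- compute_features(acc)                    # 36 features / window
train <- train[!is.na(train$label), ]             # pure windows only

fit <- train_forest(train, n_trees = 1000, seed = 1)
fit
#> Random-forest behaviour model: 1000 trees, mtry 6, seed 1
#> OOB error rate: 0.000
#> OOB confusion (rows observed, columns predicted):
#>         feeding resting running walking
#> feeding    1035       0       0       0
#> resting       0    5693       0       0
#> running       0       0      21       0
#> walking       0       0       0     367
```

The zero OOB error reflects how cleanly separated the synthetic behaviours
are, not field performance. Predicting a second simulated day and scoring
against its truth labels:

```r
sched2 <- simulate_schedule(6 * 3600, seed = 99)
test   <- compute_features(simulate_accel(sched2, seed = 100))
test   <- test[!is.na(test$label), ]
pred   <- predict_behaviors(fit, test)
m <- classification_metrics(confusion(test$label, pred))
round(m$per_class[, c("precision", "recall", "mcc")], 3)
#>   precision recall mcc
#> 1         1      1   1
#> 2         1      1   1
#> 3         1      1   1
#> 4         1      1   1

labels <- data.frame(bear_id = "F1", time = test$window_start,
                     label = merge_feedwalk(pred))
bouts <- detect_bouts(labels, "running")
nrow(bouts); mean(bouts$duration_s)
#> [1] 10
#> [1] 11.1

daily_metrics(bouts, labels,
              demographics = data.frame(bear_id = "F1",
                                        group = "adult_solitary_female"))
#>         date      period n_running_bouts n_bouts_legal_hours prop_legal
#> 1 2021-08-01 pre_hunting              10                   1        0.1
```

So on this simulated pre-hunting day the bear ran 10 times for about 11 s
on average, and 10% of those bouts started inside legal hunting hours.

## Documentation

The methods vignette (`vignettes/bear-accelerometry.Rmd`) documents the
signal conventions, classifier settings, solar/bout rules, the design of
the synthetic generator and known limitations.
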