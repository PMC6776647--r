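## Shared fixtures, built lazily and cached for the whole test run.
## Training-set sizes are kept small so the full suite runs in minutes on
## one CPU; seeds are fixed so every fixture is reproducible.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- builder()
  .fixtures[[name]]
}

## survey-resolution template: 1 m/px, default sea state and posture mix
testTemplate <- function() sceneSpec()

testClassificationSet <- function() {
  fixture("cls_set", function()
    generateClassificationDataset(60, patch_size = 71, seed = 5,
                                  pixel_sizes = 1.0))
}

testHeldOutSet <- function() {
  fixture("cls_heldout", function()
    generateClassificationDataset(30, patch_size = 71, seed = 99,
                                  pixel_sizes = 1.0))
}

testDetectionSet <- function() {
  fixture("det_set", function()
    generateDetectionDataset(80, patch_size = 71, seed = 21,
                             pixel_sizes = 1.0))
}

## desk-scale training: paper-recipe defaults with the documented epsilon
## override that lets RMSProp converge on a model this small
testTrainingConfig <- function(seed = 3L, epochs = 30L) {
  trainingConfig(epochs = epochs, seed = seed, epsilon = 1e-3)
}

testClassifier <- function() {
  fixture("classifier", function()
    trainPresenceClassifier(testClassificationSet(), testTrainingConfig(),
                            augment = augmentConfig(), augment_repeats = 2L))
}

testDetector <- function() {
  fixture("detector", function()
    trainDetector(testDetectionSet(), testTrainingConfig(seed = 4L)))
}

## a small surveyed site shared by cascade tests
testSite <- function() {
  fixture("site", function()
    generateSurveySite(seed = 11L, n_scenes = 6L))
}

## macro-F1 over the three classes for label/prediction vectors
macroF1 <- function(truth, pred) {
  mean(vapply(unique(truth), function(cl) {
    tp <- sum(pred == cl & truth == cl)
    fp <- sum(pred == cl & truth != cl)
    fn <- sum(pred != cl & truth == cl)
    precisionRecallF1(tp, fp, fn)$f1
  }, numeric(1)))
}

predictLabels <- function(classifier, patches) {
  vapply(patches, function(p) names(which.max(classifyCell(classifier, p))),
         character(1))
}
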