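# Shared fixtures, built once per test run and memoised.
#
# All image fixtures are generated at a reduced working resolution of
# 2 px/mm (the analysis is resolution-agnostic; the native scale is
# 12 px/mm) to keep scene sizes small.

.fixtures <- new.env(parent = emptyenv())

getFixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# four default-condition scenes, two per habitat
smallScenes <- function() getFixture("smallScenes", function()
  generateDataset(2, 2, seed = 7, pxPerMm = 2))

# their pooled feature table (120 rows)
smallTable <- function() getFixture("smallTable", function()
  buildFeatureTable(smallScenes(), seed = 7))

# a mid-sized default-condition dataset for statistics (6 + 6 nests)
midTable <- function() getFixture("midTable", function()
  buildFeatureTable(generateDataset(6, 6, seed = 21, pxPerMm = 2),
                    seed = 21))

# colour-matched dataset: eggs differ from backgrounds in texture only
# (per-channel egg-minus-background offset forced to zero)
matchedTable <- function() getFixture("matchedTable", function()
  buildFeatureTable(
    generateDataset(6, 6, seed = 11, pxPerMm = 2, eggOffset = c(0, 0, 0)),
    seed = 11))

defaultSystem <- function() getFixture("system", spectralSystem)

# simple synthetic LOO result for classifier-free discriminability tests
makeLoo <- function(labels, probs, nest = "n1") {
  structure(data.frame(nest_id = nest, label = labels, prob = probs,
                       stringsAsFactors = FALSE),
            class = c("LOOResult", "data.frame"))
}
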