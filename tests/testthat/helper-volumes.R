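# tiny fixture builders shared across tests; all volumes are generated in
# code, never stored on disk

tinyGrid <- c(16L, 32L, 32L)

tinyPhantomConfig <- function(...) phantomConfig(grid = tinyGrid, ...)

# a hand-built 10-voxel "volume" (as a 1 x 2 x 5 array) with a 6-voxel body
handCase <- function() {
  labels <- array(0L, c(1, 2, 5))
  labels[1, 1, 1:3] <- 1L           # other tissue
  labels[1, 2, 1:2] <- 6L           # ptv
  labels[1, 2, 3]   <- 4L           # heart
  truth <- array(0, c(1, 2, 5))
  truth[1, 1, 1:3] <- c(100, 300, 450)
  truth[1, 2, 1:2] <- c(5200, 4900)
  truth[1, 2, 3]   <- 800
  pred <- truth
  pred[1, 1, 1] <- 150              # +50
  pred[1, 2, 1] <- 5000             # -200
  pred[1, 2, 3] <- 600              # -200
  sp <- c(5, 5, 5)
  list(labels = LabelVolume(labels, sp),
       truth = DoseVolume(truth, sp), pred = DoseVolume(pred, sp))
}

# replace a leaf in a nested list by path (names or indices)
.setLeaf <- function(tree, path, value) {
  if (!length(path)) return(value)
  tree[[path[[1]]]] <- .setLeaf(tree[[path[[1]]]], path[-1], value)
  tree
}

# consistent random 3D permutation of a set of same-shaped arrays
permuteAll <- function(arrs, seed = 42) {
  d <- dim(arrs[[1]])
  perm <- withr::with_seed(seed, sample.int(prod(d)))
  lapply(arrs, function(a) array(a[perm], d))
}
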