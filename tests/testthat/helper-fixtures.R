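# Shared tiny configurations and a session-cached synthetic dataset.

tiny_net_cfg <- function(input = c(32L, 32L)) {
  network_config(depths = c(1L, 1L, 1L, 1L), dims = c(8L, 8L, 16L, 16L),
                 input_size = input)
}

desk_net_cfg <- function() {
  network_config(depths = c(1L, 1L, 2L, 1L), dims = c(16L, 32L, 64L, 128L),
                 input_size = c(64L, 64L))
}

.fixture_env <- new.env(parent = emptyenv())

# 6 patients x 4 images at 64x64, generated once per test session
shared_dataset <- function() {
  if (is.null(.fixture_env$man)) {
    .fixture_env$man <- generate_dataset(
      n_patients = 6, images_per_patient = 4, thrombus_fraction = 0.5,
      size = c(64L, 64L), seed = 11L,
      out_dir = file.path(tempdir(), "laa_shared_ds"))
  }
  .fixture_env$man
}

# a random binary mask and probability map pair
random_pair <- function(h = 32, w = 32) {
  gt <- matrix(as.numeric(runif(h * w) > 0.7), h, w)
  prob <- matrix(runif(h * w), h, w)
  list(gt = gt, prob = prob, pred = (prob > 0.5) * 1)
}

# brute-force confusion counting by explicit double loop
oracle_confusion <- function(pred, gt) {
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_len(nrow(gt))) {
    for (j in seq_len(ncol(gt))) {
      if (pred[i, j] == 1 && gt[i, j] == 1) tp <- tp + 1L
      else if (pred[i, j] == 1 && gt[i, j] == 0) fp <- fp + 1L
      else if (pred[i, j] == 0 && gt[i, j] == 0) tn <- tn + 1L
      else fn <- fn + 1L
    }
  }
  list(tp = tp, fp = fp, tn = tn, fn = fn)
}

# all-pairs Mann-Whitney AUC oracle (ties count 1/2)
oracle_auc <- function(prob, gt) {
  pos <- prob[gt == 1]
  neg <- prob[gt == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(cmp)
}

# union-find connected-component count, 4-neighborhood (independent of the
# package's BFS labeler)
oracle_ncomp <- function(m) {
  h <- nrow(m)
  w <- ncol(m)
  parent <- seq_len(h * w)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  union <- function(a, b) {
    ra <- find(a)
    rb <- find(b)
    if (ra != rb) parent[ra] <<- rb
  }
  for (j in seq_len(w)) {
    for (i in seq_len(h)) {
      if (m[i, j] == 0) next
      if (i > 1 && m[i - 1, j] == 1) union(i + h * (j - 1), i - 1 + h * (j - 1))
      if (j > 1 && m[i, j - 1] == 1) union(i + h * (j - 1), i + h * (j - 2))
    }
  }
  roots <- vapply(which(m == 1), function(i) as.integer(find(i)), 0L)
  length(unique(roots))
}
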