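# small fixtures shared across tests; everything is generated in code

tiny_ct <- function(hu = 0, dims = c(2L, 8L, 8L), spacing = c(0.7, 0.7),
                    thick = 3, id = "T01") {
  ct_volume(array(hu, dims), spacing, thick, subject_id = id)
}

# phantom spec small enough for per-test training smoke runs
tiny_phantom_spec <- function(...) {
  phantom_spec(image_size = c(32L, 32L), n_slices = 3L, ...)
}

tiny_subjects <- function(n, seed = 5, spec = tiny_phantom_spec()) {
  coh <- generate_cohort(spec, n, seed = seed)
  lapply(coh$subjects, function(s)
    list(subject_id = s$meta$subject_id, ct = s$ct, mask = s$mask))
}

# independent confusion-matrix oracle for binary masks
oracle_binary_metrics <- function(pred, truth) {
  tp <- 0; fp <- 0; fn <- 0; tn <- 0
  for (i in seq_along(pred)) {
    if (pred[i] == 1 && truth[i] == 1) tp <- tp + 1
    else if (pred[i] == 1 && truth[i] == 0) fp <- fp + 1
    else if (pred[i] == 0 && truth[i] == 1) fn <- fn + 1
    else tn <- tn + 1
  }
  list(tp = tp, fp = fp, fn = fn, tn = tn,
       precision = if (tp + fp > 0) tp / (tp + fp) else 0,
       recall = if (tp + fn > 0) tp / (tp + fn) else 0,
       dice = if (2 * tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else 1,
       accuracy = (tp + tn) / length(pred))
}

# independent per-pixel summation oracle for the generalized dice score
oracle_generalized_dice <- function(pred, truth, eps = 1e-6) {
  K <- dim(pred)[length(dim(pred))]
  num <- 0; den <- 0
  pm <- matrix(pred, ncol = K)
  tm <- matrix(truth, ncol = K)
  for (k in seq_len(K)) {
    inter <- 0; ps <- 0; ts <- 0
    for (i in seq_len(nrow(pm))) {
      inter <- inter + pm[i, k] * tm[i, k]
      ps <- ps + pm[i, k]
      ts <- ts + tm[i, k]
    }
    w <- 1 / (ts + eps)^2
    num <- num + w * inter
    den <- den + w * (ps + ts)
  }
  2 * num / den
}

# independent midrank-then-Pearson Spearman oracle
oracle_spearman <- function(x, y) {
  rx <- rank(x, ties.method = "average")
  ry <- rank(y, ties.method = "average")
  mx <- mean(rx); my <- mean(ry)
  sum((rx - mx) * (ry - my)) /
    sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
}

# brute-force flood fill component labelling (reference for the compiled one)
oracle_components <- function(mask, connectivity = 8L) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  cur <- 0L
  nbrs <- if (connectivity == 8L)
    rbind(c(-1,0), c(1,0), c(0,-1), c(0,1), c(-1,-1), c(-1,1), c(1,-1), c(1,1))
  else rbind(c(-1,0), c(1,0), c(0,-1), c(0,1))
  for (j in seq_len(W)) for (i in seq_len(H)) {
    if (mask[i, j] == 0 || lab[i, j] != 0) next
    cur <- cur + 1L
    queue <- list(c(i, j)); lab[i, j] <- cur
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (q in seq_len(nrow(nbrs))) {
        ni <- p[1] + nbrs[q, 1]; nj <- p[2] + nbrs[q, 2]
        if (ni >= 1 && ni <= H && nj >= 1 && nj <= W &&
            mask[ni, nj] != 0 && lab[ni, nj] == 0) {
          lab[ni, nj] <- cur
          queue[[length(queue) + 1L]] <- c(ni, nj)
        }
      }
    }
  }
  lab
}
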