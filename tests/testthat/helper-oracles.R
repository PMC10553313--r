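# Independent brute-force recomputation of the macro metric suite using
# per-class loops only; the oracle the metrics module is audited against.
ref_metrics_suite <- function(cm) {
  C <- nrow(cm)
  rec <- numeric(C)
  pre <- numeric(C)
  for (cc in seq_len(C)) {
    tp <- cm[cc, cc]
    fn <- 0
    fp <- 0
    for (k in seq_len(C)) {
      if (k == cc) next
      fn <- fn + cm[cc, k]
      fp <- fp + cm[k, cc]
    }
    rec[cc] <- if (tp + fn > 0) tp / (tp + fn) else 0
    pre[cc] <- if (tp + fp > 0) tp / (tp + fp) else 0
  }
  mrec <- sum(rec) / C
  mpre <- sum(pre) / C
  s <- rec
  for (cc in seq_len(C)) if (s[cc] == 0) s[cc] <- 0.001
  gm <- 1
  for (cc in seq_len(C)) gm <- gm * s[cc]
  gm <- gm^(1 / C)
  tp_all <- 0
  for (cc in seq_len(C)) tp_all <- tp_all + cm[cc, cc]
  list(rec = rec, pre = pre, MRec = mrec, MPre = mpre,
       MF1 = if (mpre + mrec > 0) 2 * mpre * mrec / (mpre + mrec) else 0,
       Acc = tp_all / sum(cm), GM = gm)
}

# Hard 0/1 box indicator on a pixel grid (the infinite-steepness limit of
# the soft mask). Pixel-area convention: pixel x spans [x-0.5, x+0.5], so
# a pixel is inside when its centre lies within half a pixel of the box.
hard_box_indicator <- function(box, H, W) {
  outer(0:(H - 1), 0:(W - 1), function(y, x)
    as.numeric(abs(x - box$tx) < box$tl + 0.5 &
                 abs(y - box$ty) < box$tl + 0.5))
}

# Small random probability matrix on the simplex.
random_simplex_rows <- function(n, C) {
  raw <- matrix(rexp(n * C), n, C)
  raw / rowSums(raw)
}

# Tiny deterministic dataset for fast training-path tests.
tiny_dataset <- function(n_train = 6, n_val = 4, n_classes = 2, seed = 42) {
  sp <- scene_spec(n_classes = n_classes, seed = seed)
  generate_dataset(sp, n_train = n_train, n_validation = n_val, n_test = 2)
}

tiny_model <- function(seed = 1, dropout = 0.45) {
  init_cascade(backbone_config(channels = c(4, 4, 4, 8, 8),
                               n_classes = 2, dropout_rate = dropout),
               seed = seed)
}
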