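# shared fixture builders

# a small three-group cohort configuration (7/5/4 patients) for fast tests
small_config <- function(seed = NULL, ...) {
  g <- default_groups()
  sizes <- c(7L, 5L, 4L)
  for (i in seq_along(g)) g[[i]]$n <- sizes[i]
  cohort_config(groups = g, seed = seed, ...)
}

# an la_curve built directly from sampled values over one RR interval
make_curve <- function(v, location = "mitral_junction", rr_ms = 1000) {
  n <- length(v)
  out <- data.frame(location = location, phase_index = seq_len(n),
                    time_ms = (seq_len(n) - 1) / n * rr_ms,
                    vmax_cm_s = v, stringsAsFactors = FALSE)
  attr(out, "rr_ms") <- rr_ms
  class(out) <- c("la_curve", "data.frame")
  out
}

# brute-force AUC oracle: (concordant + ties/2) / (n_pos * n_neg)
auc_pairs <- function(scores, positive) {
  pos <- scores[positive]; neg <- scores[!positive]
  tot <- 0
  for (p in pos) tot <- tot + sum(p > neg) + 0.5 * sum(p == neg)
  tot / (length(pos) * length(neg))
}

# random positive velocity quads for property loops
random_quads <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(vE = runif(n, 20, 90), vA = runif(n, 15, 70),
             vS = runif(n, 15, 60), vD = runif(n, 15, 55))
}
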