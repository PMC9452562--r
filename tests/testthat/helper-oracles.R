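# Independent brute-force oracles used across the suite. These deliberately
# re-derive each quantity from first principles, sharing no code with the
# package implementation.

# mRECIST banding by explicit if-chains
oracle_mrecist <- function(x) {
  vapply(x, function(v) {
    if (v <= -95) "CR" else if (v <= -30) "PR" else if (v <= 20) "SD" else "PD"
  }, character(1))
}

# RTV banding by explicit if-chains
oracle_rtv_band <- function(rtv) {
  vapply(rtv, function(v) {
    if (v > 1.2) "PD" else if (v >= 0.7) "SD" else "PR/CR"
  }, character(1))
}

# copy-number log-ratio banding
oracle_cn_band <- function(lr) {
  vapply(lr, function(v) {
    if (v < -1) "deep_del" else if (v < -0.4) "shallow_del" else "unaltered"
  }, character(1))
}

# Youden cutoff by exhaustive enumeration over every candidate threshold
# (each distinct score value), mirroring the documented tie rule: maximum J,
# then maximum sensitivity, then lowest threshold.
oracle_youden <- function(scores, labels01, high_is_positive = TRUE) {
  s <- if (high_is_positive) scores else -scores
  cand <- sort(unique(s))
  rows <- lapply(cand, function(t) {
    called_pos <- s >= t
    sens <- sum(called_pos & labels01 == 1) / sum(labels01 == 1)
    spec <- sum(!called_pos & labels01 == 0) / sum(labels01 == 0)
    c(threshold = if (high_is_positive) t else -t, j = sens + spec - 1,
      sens = sens, spec = spec)
  })
  m <- do.call(rbind, rows)
  ord <- order(-m[, "j"], -m[, "sens"], m[, "threshold"])
  as.list(m[ord[1], ])
}

# AUC by pair counting (Mann-Whitney identity)
oracle_auc <- function(scores, labels01) {
  pos <- scores[labels01 == 1]
  neg <- scores[labels01 == 0]
  pairs <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  mean(pairs)
}

# Two-sided Fisher p by explicit hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  a <- tab[1, 1]
  r1 <- sum(tab[1, ])
  r2 <- sum(tab[2, ])
  c1 <- sum(tab[, 1])
  n <- r1 + r2
  support <- max(0, c1 - r2):min(r1, c1)
  probs <- stats::dhyper(support, r1, r2, c1)
  p_obs <- stats::dhyper(a, r1, r2, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# BH step-up from the definitional formula
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  q[o] <- p[o] * m / seq_len(m)
  # enforce monotonicity from the largest p down
  for (i in (m - 1):1) q[o[i]] <- min(q[o[i]], q[o[i + 1]])
  pmin(q, 1)
}

# geNorm M by direct double loop
oracle_genorm_m <- function(ct_mat, candidates) {
  sapply(candidates, function(j) {
    others <- setdiff(candidates, j)
    mean(sapply(others, function(k) stats::sd(ct_mat[k, ] - ct_mat[j, ])))
  })
}

# tiny caliper series builder
make_series <- function(days, volumes, model = "M1", animal = "a1",
                        arm = "treated", aspect = 1.25) {
  w <- (6 * volumes / (pi * aspect))^(1 / 3)
  tibble::tibble(
    model_id = model, animal_id = animal, arm = arm,
    day = days, length_mm = aspect * w, width_mm = w
  )
}
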