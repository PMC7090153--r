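# Independent brute-force oracles used to cross-check the implementation.

# AUC as the fraction of concordant event/non-event pairs (ties count 1/2).
auc_bruteforce <- function(pred, y) {
  p1 <- pred[y == 1]
  p0 <- pred[y == 0]
  num <- 0
  for (a in p1) for (b in p0) num <- num + (a > b) + 0.5 * (a == b)
  num / (length(p1) * length(p0))
}

# Two-sided Fisher exact p for a 2x2 table by hypergeometric enumeration:
# sum the probabilities of all tables (same margins) no more likely than
# the observed one.
fisher_bruteforce <- function(tab) {
  m <- sum(tab[1, ]); n <- sum(tab[2, ]); k <- sum(tab[, 1])
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(tab[1, 1], m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Exact two-sided Mann-Whitney p by full enumeration of group assignments.
mw_bruteforce <- function(x0, x1) {
  pooled <- c(x0, x1)
  n0 <- length(x0)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n0)])
  combs <- utils::combn(length(pooled), n0)
  w_all <- apply(combs, 2, function(idx) sum(r[idx]))
  mu <- n0 * (length(pooled) + 1) / 2
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# Surface-weighted gEUD straight from boundary faces (no histogramming).
geud_faces <- function(dose, omega, n) {
  bf <- skinNTCP:::boundary_faces(omega, dose)
  w <- bf$area_cm2 / sum(bf$area_cm2)
  (sum(w * bf$dose_gy^(1 / n)))^n
}

# Youden scan over the midpoints of adjacent distinct observed values
# (the same threshold space the implementation searches).
youden_bruteforce <- function(values, y) {
  v <- sort(unique(values))
  cand <- (utils::head(v, -1) + utils::tail(v, -1)) / 2
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  js <- vapply(cand, function(ct) {
    sum(values > ct & y == 1) / n1 + sum(values <= ct & y == 0) / n0 - 1
  }, numeric(1))
  max(js)
}

# Small analytic sphere phantom on an isotropic grid.
sphere_phantom <- function(R_mm = 40, spacing = 2, n = NULL, couch = FALSE) {
  if (is.null(n)) n <- ceiling((2 * R_mm) / spacing) + 8
  ctr <- (n - 1) * spacing / 2
  make_phantom(phantom_spec(shape = rep(n, 3), spacing = rep(spacing, 3),
                            body = "sphere", semi_axes = R_mm,
                            center = rep(ctr, 3), couch = couch))
}

uniform_dose <- function(mask, gy) {
  image_volume(array(gy, dim(mask$data)), mask$spacing, mask$origin,
               units = "Gy")
}

# Relative DSH evaluated at a dose (linear interpolation).
dsh_value <- function(x, dose) skinNTCP:::dsh_at(x, dose)
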