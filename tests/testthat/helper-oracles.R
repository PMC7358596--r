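## Shared fixtures built in code, plus brute-force oracles kept
## independent of the package's own linear-algebra route.

## Hand-written 12-record, 2-feature, 3-class table with unequal group
## sizes and no special structure.
toy_table <- function() {
  energy_table(
    ligand_id = sprintf("lig%02d", 1:12),
    receptor_id = "toyR",
    galpha_class = "Gi",
    dg_ligand = c(-10.2, -9.1, -11.5, -8.4, -10.9,
                  -9.8, -10.1, -9.5, -8.9,
                  -7.2, -8.8, -9.9),
    dg_gdp = c(-940, -905, -962, -881, -918,
               -771, -793, -762, -780,
               -655, -612, -690),
    dg_gtp = -500,
    bib_class = rep(c("agonist", "partial_agonist", "antagonist"),
                    c(5, 4, 3)),
    provenance = "toy"
  )
}

## Brute-force canonical LDA: eigen-decompose solve(S_W) %*% B directly
## (a different numerical route from the package's Cholesky whitening),
## then rescale to v' S_W v = 1 and orient the first coefficient positive.
oracle_lda <- function(x, cls) {
  cls <- factor(cls)
  n <- nrow(x)
  g <- nlevels(cls)
  w <- matrix(0, ncol(x), ncol(x))
  b <- matrix(0, ncol(x), ncol(x))
  grand <- colMeans(x)
  for (lev in levels(cls)) {
    xi <- x[cls == lev, , drop = FALSE]
    mi <- colMeans(xi)
    w <- w + crossprod(sweep(xi, 2, mi))
    b <- b + nrow(xi) * tcrossprod(mi - grand)
  }
  s_w <- w / (n - g)
  es <- eigen(solve(s_w) %*% b)
  v <- Re(es$vectors[, which.max(Re(es$values))])
  v <- v / sqrt(drop(t(v) %*% s_w %*% v))
  if (v[1] < 0) v <- -v
  list(coefficients = v, constant = -drop(v %*% grand))
}

## Manual one-way sums-of-squares decomposition.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  grand <- mean(values)
  ssb <- sum(tapply(values, groups, function(v)
    length(v) * (mean(v) - grand)^2))
  ssw <- sum(tapply(values, groups, function(v) sum((v - mean(v))^2)))
  df1 <- nlevels(groups) - 1
  df2 <- length(values) - nlevels(groups)
  f <- (ssb / df1) / (ssw / df2)
  list(f = f, p = pf(f, df1, df2, lower.tail = FALSE))
}

## Gaussian table with a class-separated dg_gdp channel and two noise
## channels whose means do not depend on class.
noise_channel_table <- function(seed, n_per_class = 60) {
  spec <- synthetic_spec(
    n = rep(n_per_class, 3),
    mean_gdp = c(-950, -760, -610), sd_gdp = rep(60, 3),
    mean_ligand = rep(-11, 3), sd_ligand = rep(2, 3),
    mean_gtp = rep(-500, 3), sd_gtp = rep(60, 3)
  )
  simulate_energy_table(spec, seed = seed)
}
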