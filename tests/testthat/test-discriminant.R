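test_that("single-feature fit reduces to the pooled-SD closed form", {
  ## three classes, identical within-group SD by construction
  vals <- c(-900, -910, -920, -760, -770, -780, -600, -610, -620)
  tab <- energy_table(
    ligand_id = sprintf("l%d", 1:9), receptor_id = "R",
    dg_gdp = vals,
    bib_class = rep(c("agonist", "partial_agonist", "antagonist"),
                    each = 3))
  fit <- fit_lda(tab, "dg_gdp")
  s_pooled <- sqrt(sum((vals - rep(tapply(vals, rep(1:3, each = 3),
                                          mean), each = 3))^2) / (9 - 3))
  expect_equal(unname(fit$coefficients), 1 / s_pooled, tolerance = 1e-12)
  expect_equal(fit$constant, -mean(vals) / s_pooled, tolerance = 1e-12)
})

test_that("two-feature fit matches the brute-force eigen oracle", {
  tab <- toy_table()
  fit <- fit_lda(tab, c("dg_gdp", "dg_ligand"))
  x <- cbind(tab$dg_gdp, tab$dg_ligand)
  oracle <- oracle_lda(x, tab$bib_class)
  expect_equal(unname(fit$coefficients), oracle$coefficients,
               tolerance = 1e-10)
  expect_equal(fit$constant, oracle$constant, tolerance = 1e-10)
})

test_that("fitted scores have unit pooled variance and zero mean", {
  specs <- list(
    list(tab = toy_table(), feats = c("dg_gdp", "dg_ligand")),
    list(tab = toy_table(), feats = "dg_gdp"),
    list(tab = simulate_energy_table(synthetic_spec(n = c(20, 20, 20)),
                                     seed = 11),
         feats = "dg_gdp")
  )
  for (sp in specs) {
    fit <- fit_lda(sp$tab, sp$feats)
    sc <- discriminant_scores(fit, sp$tab)
    cls <- sp$tab$bib_class
    expect_equal(mean(sc), 0, tolerance = 1e-8)
    ssw <- sum(tapply(sc, cls, function(v) sum((v - mean(v))^2)))
    expect_equal(ssw / (length(sc) - length(unique(cls))), 1,
                 tolerance = 1e-8)
    expect_gt(fit$coefficients[["dg_gdp"]], 0)
    ## agonists bind G-alpha-GDP most strongly -> lowest centroid
    expect_lt(fit$class_centroids[["agonist"]],
              fit$class_centroids[["partial_agonist"]])
    expect_lt(fit$class_centroids[["partial_agonist"]],
              fit$class_centroids[["antagonist"]])
  }
})

test_that("coefficients are affine-equivariant in the energies", {
  tab <- toy_table()
  fit <- fit_lda(tab, "dg_gdp")
  shift <- as.data.frame(tab)
  shift$dg_gdp <- shift$dg_gdp - 40          # stays negative
  shifted <- do.call(energy_table, c(shift, provenance = "shifted"))
  fit_s <- fit_lda(shifted, "dg_gdp")
  expect_equal(fit_s$coefficients, fit$coefficients, tolerance = 1e-10)
  expect_equal(fit_s$constant,
               fit$constant + 40 * fit$coefficients[["dg_gdp"]],
               tolerance = 1e-10)

  scale <- as.data.frame(tab)
  scale$dg_gdp <- scale$dg_gdp * 3
  scaled <- do.call(energy_table, c(scale, provenance = "scaled"))
  fit_k <- fit_lda(scaled, "dg_gdp")
  expect_equal(unname(fit_k$coefficients),
               unname(fit$coefficients) / 3, tolerance = 1e-10)
})

test_that("fit agrees with an independent reference implementation", {
  skip_if_not_installed("MASS")
  tab <- toy_table()
  fit <- fit_lda(tab, c("dg_gdp", "dg_ligand"))
  ref <- MASS::lda(cls ~ dg_gdp + dg_ligand,
                   data.frame(cls = tab$bib_class,
                              dg_gdp = tab$dg_gdp,
                              dg_ligand = tab$dg_ligand))
  ## same axis up to sign under the same unit within-variance scaling
  expect_equal(abs(unname(fit$coefficients)),
               abs(unname(ref$scaling[, 1])), tolerance = 1e-8)
})

test_that("degenerate inputs raise the documented errors", {
  tab <- toy_table()
  one <- as.data.frame(tab)[c(1, 6, 10), ]           # 1 record per class
  one_tab <- do.call(energy_table, c(one, provenance = "tiny"))
  expect_error(fit_lda(one_tab, "dg_gdp"), "degenerate")

  dup <- as.data.frame(tab)
  dup$dg_ligand <- dup$dg_gdp                        # collinear features
  dup_tab <- do.call(energy_table, c(dup, provenance = "dup"))
  expect_error(fit_lda(dup_tab, c("dg_gdp", "dg_ligand")), "singular|collinear")

  expect_error(fit_lda(tab, "dg_banana"), "unknown feature")
})

test_that("score_to_energy inverts single-feature scoring exactly", {
  fit <- fit_lda(toy_table(), "dg_gdp")
  sc <- discriminant_scores(fit, toy_table())
  expect_equal(score_to_energy(fit, sc), toy_table()$dg_gdp,
               tolerance = 1e-10)
  expect_equal(score_to_energy(fit, fit$constant), 0)
  multi <- fit_lda(toy_table(), c("dg_gdp", "dg_ligand"))
  expect_error(score_to_energy(multi, 0), "single-feature")
})

test_that("weighted mean cutoff follows the exact formula", {
  expect_equal(weighted_mean_cutoff(1.0, 10, 3.0, 30), 2.5)
  expect_equal(weighted_mean_cutoff(-7, 3, -7, 17), -7)
  expect_error(weighted_mean_cutoff(1, 0, 2, 5))
})

test_that("cutoffs are weighted centroid means, inverted to energies", {
  ## symmetric classes with equal n at centroids -1, 0, +1 give +-0.5
  tab <- simulate_energy_table(
    synthetic_spec(n = c(400, 400, 400),
                   mean_gdp = c(-900, -780, -660), sd_gdp = rep(5, 3)),
    seed = 3)
  fit <- fit_lda(tab, "dg_gdp")
  co <- derive_cutoffs(fit)
  cen <- fit$class_centroids
  expect_equal(co$theta_antago_pa,
               (cen[["antagonist"]] + cen[["partial_agonist"]]) / 2,
               tolerance = 1e-12)
  expect_equal(co$theta_pa_ago,
               (cen[["partial_agonist"]] + cen[["agonist"]]) / 2,
               tolerance = 1e-12)
  expect_lt(co$theta_pa_ago, co$theta_antago_pa)
  expect_lt(co$energy_pa_ago, co$energy_antago_pa)
  ## energy cutoffs are the inverse images of the score cutoffs
  expect_equal(score_to_energy(fit, co$theta_antago_pa),
               co$energy_antago_pa, tolerance = 1e-12)

  ## unequal-n case matches direct recomputation
  tab2 <- simulate_energy_table(
    synthetic_spec(n = c(50, 10, 25),
                   mean_gdp = c(-900, -780, -660), sd_gdp = rep(40, 3)),
    seed = 4)
  fit2 <- fit_lda(tab2, "dg_gdp")
  co2 <- derive_cutoffs(fit2)
  cc <- centroids(fit2, tab2)
  w <- with(cc, (centroid[class == "antagonist"] * n[class == "antagonist"] +
                 centroid[class == "partial_agonist"] *
                   n[class == "partial_agonist"]) /
              (n[class == "antagonist"] + n[class == "partial_agonist"]))
  expect_equal(co2$theta_antago_pa, w, tolerance = 1e-12)
})

test_that("centroids are per-class score means with matching counts", {
  tab <- toy_table()
  fit <- fit_lda(tab, "dg_gdp")
  cc <- centroids(fit, tab)
  sc <- discriminant_scores(fit, tab)
  for (i in seq_len(nrow(cc))) {
    expect_equal(cc$centroid[i],
                 mean(sc[tab$bib_class == cc$class[i]]))
    expect_equal(cc$n[i], sum(tab$bib_class == cc$class[i]))
  }
  ## degenerate: one record per class -> centroid equals the record score
  one <- as.data.frame(tab)[c(1, 6, 10), ]
  one_tab <- do.call(energy_table, c(one, provenance = "tiny"))
  cc1 <- centroids(fit, one_tab)
  expect_equal(cc1$centroid, discriminant_scores(fit, one_tab))
})

test_that("backward elimination keeps the class-separated channel", {
  ## At an F-to-remove threshold of 10 a pure-noise channel survives
  ## with probability ~1e-4 (upper F tail), so exact retention of the
  ## informative channel is expected on every seed. At the default
  ## threshold 2.71 a noise channel survives with probability ~7% per
  ## channel by construction of the F test, so there the check is that
  ## the informative channel is never dropped and noise survives only
  ## at about the nominal rate.
  extra_default <- 0L
  for (seed in 1:20) {
    tab <- noise_channel_table(seed)
    be <- backward_eliminate(tab, c("dg_ligand", "dg_gdp", "dg_gtp"),
                             f_to_remove = 10)
    expect_identical(be$retained, "dg_gdp", label = paste("seed", seed))
    be_def <- backward_eliminate(tab, c("dg_ligand", "dg_gdp", "dg_gtp"))
    expect_true("dg_gdp" %in% be_def$retained,
                label = paste("default threshold, seed", seed))
    extra_default <- extra_default + length(be_def$retained) - 1L
  }
  ## 40 noise channel-seed draws at ~7% nominal survival each
  expect_lte(extra_default, 12L)
})

test_that("elimination trace partitions the feature set", {
  tab <- noise_channel_table(99)
  be <- backward_eliminate(tab, c("dg_ligand", "dg_gdp", "dg_gtp"))
  expect_setequal(c(be$retained, be$trace$feature_removed),
                  c("dg_ligand", "dg_gdp", "dg_gtp"))
  expect_true(all(be$trace$partial_f < be$f_to_remove))
  ## strong single-feature input: retained unchanged, empty trace
  be1 <- backward_eliminate(tab, "dg_gdp")
  expect_identical(be1$retained, "dg_gdp")
  expect_equal(nrow(be1$trace), 0)
  ## pure-noise features with a liberal threshold eliminate everything
  noise_only <- backward_eliminate(tab, c("dg_ligand", "dg_gtp"),
                                   f_to_remove = 1e6)
  expect_true(noise_only$empty_model)
})

test_that("single-feature partial F equals the one-way ANOVA F", {
  tab <- toy_table()
  be <- backward_eliminate(tab, "dg_gdp", f_to_remove = 1e9)
  av <- one_way_anova(tab$dg_gdp, tab$bib_class)
  expect_equal(be$trace$partial_f[1], av$f_stat, tolerance = 1e-10)
})

test_that("model serialisation round-trips the key parameters", {
  fit <- fit_lda(toy_table(), "dg_gdp")
  js <- jsonlite::fromJSON(model_to_json(fit, derive_cutoffs(fit)))
  expect_equal(js$coefficients$dg_gdp, unname(fit$coefficients))
  expect_equal(js$constant, fit$constant)
  expect_equal(js$schema, "gpcrtriage/discriminant_model/1")
  expect_equal(js$cutoffs$theta_antago_pa,
               derive_cutoffs(fit)$theta_antago_pa)
})
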