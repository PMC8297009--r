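test_that("degrees of freedom and free-parameter counts are consistent", {
  expected_df <- c(A_correlated = 41L, B_bifactor = 30L,
                   C_revised_bifactor = 35L, D_single = 44L)
  for (mid in model_ids()) {
    spec <- build_model(mid)
    expect_identical(model_df(spec), expected_df[[mid]])
    # df + free parameters must exhaust the 66 non-redundant moments
    expect_identical(model_df(spec) + n_free_parameters(spec), 66L)
  }
})

test_that("model templates encode the four structures", {
  a <- build_model("A_correlated")
  expect_equal(sum(a$loading_pattern), 11)
  expect_equal(nrow(a$free_factor_correlations), 3)
  expect_false("p" %in% a$factor_labels)

  d <- build_model("D_single")
  expect_equal(sum(d$loading_pattern), 11)
  expect_equal(nrow(d$free_factor_correlations), 0)

  cc <- build_model("C_revised_bifactor")
  tht <- disorder_domains()$tht
  expect_true(all(cc$loading_pattern[tht, "p"]))
  expect_false(any(cc$loading_pattern[tht, c("Ext", "Int")]))
  expect_setequal(cc$factor_labels, c("p", "Ext", "Int"))

  b <- build_model("B_bifactor")
  expect_equal(sum(b$loading_pattern), 22)
  expect_equal(nrow(b$fixed_orthogonal), 3)
  expect_true(all(b$fixed_orthogonal[, 1] == "p"))

  # every indicator loads somewhere, in every model
  for (mid in model_ids())
    expect_true(all(rowSums(build_model(mid)$loading_pattern) >= 1))

  expect_error(build_model("E_nonexistent"))
})

test_that("implied covariance matches hand-computed moments", {
  # two-indicator single factor: off-diagonal is the loading product
  spec <- single_factor_toy(2)
  par <- make_params(spec, matrix(c(.5, .5), 2, 1))
  S <- implied_covariance(spec, par)
  expect_equal(S[1, 2], 0.25)
  expect_equal(diag(S), c(y1 = 1, y2 = 1))

  # Dunedin-cohort revised bifactor: mania and schizophrenia share only the
  # general factor, so their covariance is the product of their p loadings
  pc <- generating_parameters("caspi")
  Sc <- implied_covariance(build_model("C_revised_bifactor"), pc)
  expect_equal(Sc["mania", "schiz"], 0.973 * 0.819, tolerance = 1e-12)

  # correlated-factors fixture: cross-domain covariance goes through the
  # factor correlation (lambda_alc,Ext * phi_ExtInt * lambda_dep,Int)
  pa <- generating_parameters("caspi", "correlated")
  Sa <- implied_covariance(build_model("A_correlated"), pa)
  expect_equal(Sa["alc", "dep"], 0.733 * 0.328 * 0.972, tolerance = 1e-12)
})

test_that("standardized generating fixtures have unit implied diagonal", {
  for (set in c("caspi", "simdata")) {
    for (model in c("revised_bifactor", "correlated")) {
      par <- generating_parameters(set, model)
      spec <- build_model(if (model == "revised_bifactor")
        "C_revised_bifactor" else "A_correlated")
      S <- implied_covariance(spec, par)
      expect_true(all(abs(diag(S) - 1) < 1e-12),
                  label = paste(set, model, "unit diagonal"))
      expect_true(all(abs(par$loadings) <= 1))
      expect_true(all(par$residual_variances > 0))
    }
  }
})

test_that("implied covariance commutes with indicator reordering", {
  spec <- build_model("C_revised_bifactor")
  par <- generating_parameters("simdata")
  S <- implied_covariance(spec, par)
  perm <- sample(11)
  spec2 <- spec
  spec2$indicators <- spec$indicators[perm]
  spec2$loading_pattern <- spec$loading_pattern[perm, ]
  par2 <- par
  par2$loadings <- par$loadings[perm, ]
  par2$residual_variances <- par$residual_variances[perm]
  S2 <- implied_covariance(spec2, par2)
  expect_equal(unname(S2), unname(S[perm, perm]))
})

test_that("make_params validates its inputs", {
  spec <- build_model("D_single")
  bad <- matrix(.5, 11, 1)
  ok <- make_params(spec, bad)
  expect_s3_class(ok, "bfs_params")
  specC <- build_model("C_revised_bifactor")
  L <- generating_parameters("caspi")$loadings
  L["ocd", "Ext"] <- .3  # off-pattern
  expect_error(make_params(specC, L), "pattern")
  Phi <- diag(3); Phi[1, 1] <- 2
  expect_error(make_params(specC, generating_parameters("caspi")$loadings,
                           Phi), "diagonal")
})

test_that("covariate target fixtures are complete and bounded", {
  for (set in c("caspi", "simdata")) {
    tg <- covariate_targets(set)
    expect_identical(dim(tg), c(4L, 3L))
    expect_true(all(is.finite(tg)))
    expect_true(all(abs(tg) < 1))
    # each covariate's multiple R^2 on the factors must stay below 1
    phi <- generating_parameters(set)$factor_correlations
    r2 <- apply(tg, 1, function(r) sum(r * solve(phi, r)))
    expect_true(all(r2 < 1))
  }
})
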