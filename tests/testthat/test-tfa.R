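# The feasibility pipeline: best-case quotients, determinism, bounds,
# pathway additivity, mode comparison, reporting.

condA <- load_conditions("A")
condB <- load_conditions("B")

test_that("best-case assignment puts substrates at max and products at min", {
  rng <- list(s = list(min = 0.001, max = 0.010), p = list(min = 0.001, max = 0.010))
  cs <- condition_set("custom", 298.15, 7, metabolite_ranges = rng,
                      mode = "concentration")
  rx <- reaction_spec("toy", c(s = -1, p = 1))
  mm <- best_case_quotient(rx, cs)
  expect_equal(unname(mm["s"]), 0.010)
  expect_equal(unname(mm["p"]), 0.001)
  expect_null(attr(mm, "gamma_medium_extra"))
  # degenerate range collapses to the single value
  rng$s <- list(min = 0.004, max = 0.004)
  cs2 <- condition_set("custom", 298.15, 7, metabolite_ranges = rng,
                       mode = "concentration")
  expect_equal(unname(best_case_quotient(rx, cs2)["s"]), 0.004)
  expect_error(best_case_quotient(reaction_spec("t2", c(s = -1, q = 1)), cs),
               "no molality range")
})

test_that("conditions B adds non-participants and salts without changing Qm", {
  mmA <- best_case_quotient(gly$tpi, condA)
  mmB <- best_case_quotient(gly$tpi, condB)
  expect_equal(as.numeric(mmA), as.numeric(mmB))  # same quotient molalities
  extra <- attr(mmB, "gamma_medium_extra")
  expect_false(is.null(extra))
  expect_true(all(c("glucose", "atp", "fbp") %in% names(extra)))
  expect_false(any(c("dhap", "gap") %in% names(extra)))  # participants excluded
  # phosphate enters the gamma medium speciated
  expect_true(all(c("h2po4", "hpo4") %in% names(extra)))
})

test_that("invalid ranges are rejected", {
  expect_error(condition_set("x", 298.15, 7,
                             metabolite_ranges = list(a = list(min = 2, max = 1)),
                             mode = "activity"),
               "invalid range")
})

test_that("concentration-mode TFA is deterministic and reproduces the best-case bound", {
  t1 <- run_tfa(gly, reg$standard, condA, reg, mode = "concentration")
  t2 <- run_tfa(gly, reg$standard, condA, reg, mode = "concentration")
  expect_identical(tibble::as_tibble(t1), tibble::as_tibble(t2))
  expect_true(all(t1$status == "ok"))
  # best case is a lower bound over the ranges (randomized brute force)
  set.seed(99)
  rng <- condA$metabolite_ranges
  for (rx in gly) {
    base <- t1$dRg[t1$reaction_id == rx$reaction_id]
    parts <- setdiff(names(rx$stoichiometry), "water")
    nu <- rx$stoichiometry[parts]
    dg0 <- reg$standard$dRg0[reg$standard$reaction_id == rx$reaction_id]
    for (i in 1:200) {
      mm <- vapply(parts, function(sp)
        stats::runif(1, rng[[sp]]$min, rng[[sp]]$max), numeric(1))
      Q <- prod(mm^nu) * if (rx$h_explicit) 10^(-7 * rx$nu_h) else 1
      dg <- gibbs_of_reaction(dg0, Q, 298.15)
      expect_gte(dg, base - 1e-9)
    }
  }
})

test_that("raising a substrate molality never increases dRg in concentration mode", {
  rx <- gly$pgi
  med <- build_medium(298.15, 7, registry = reg)
  ms <- seq(1e-4, 7e-3, length.out = 8)
  dg <- vapply(ms, function(m) {
    Q <- reaction_quotient(reg, rx, c(g6p = m, f6p = 1e-4), med,
                           mode = "concentration")
    gibbs_of_reaction(2.94, as.numeric(Q), 298.15)
  }, numeric(1))
  expect_true(all(diff(dg) <= 0))
})

test_that("activity-mode TFA reports Qgamma and serializes losslessly", {
  tb <- run_tfa(gly, reg$standard, condB, reg)
  expect_true(all(tb$status == "ok"))
  expect_true(all(is.finite(tb$Qgamma)))
  expect_identical(tb$feasible, tb$dRg < 0)
  g <- glance(tb)
  expect_equal(g$n_reactions, 10L)
  td <- tidy(tb)
  expect_s3_class(td, "tbl_df")
  path <- withr::local_tempfile(fileext = ".json")
  write_tfa_report(tb, path, seed = 1)
  back <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(back$reactions$dRg, tb$dRg, tolerance = 1e-12)
  csvp <- withr::local_tempfile(fileext = ".csv")
  write_tfa_report(tb, csvp)
  expect_equal(nrow(utils::read.csv(csvp)), 10)
})

test_that("two identical activity runs are bit-identical", {
  a <- run_tfa(gly[c("tpi", "pgam")], reg$standard, condB, reg)
  b <- run_tfa(gly[c("tpi", "pgam")], reg$standard, condB, reg)
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
})

test_that("pathway additivity: TPI + GAPDH composed equals the sum", {
  molal <- c(dhap = 2e-3, gap = 1e-4, nad = 1e-3, pi = 5e-3,
             bpg = 2e-4, nadh = 1e-4)
  med <- build_medium(298.15, 7, salts = c(kcl = 0.1), registry = reg)
  comp <- reaction_spec("tpi_gapdh", c(dhap = -1, nad = -1, pi = -1,
                                       bpg = 1, nadh = 1),
                        nu_h = 1, h_explicit = TRUE)
  involved <- names(molal)
  q_of <- function(rx) {
    parts <- setdiff(names(rx$stoichiometry), "water")
    extra_ids <- setdiff(involved, parts)
    extra <- molal[extra_ids]
    if ("pi" %in% extra_ids) {
      fr <- species_fractions(pka_ladders(reg)[["pi"]], 7)
      f1 <- fr$fraction[fr$state == 1]; f2 <- fr$fraction[fr$state == 2]
      extra <- extra[names(extra) != "pi"]
      extra <- c(extra, h2po4 = f1 / (f1 + f2) * molal[["pi"]],
                 hpo4 = f2 / (f1 + f2) * molal[["pi"]])
    }
    reaction_quotient(reg, rx, molal[parts], med, mode = "activity",
                      gamma_medium_extra = extra)
  }
  dg_tpi <- gibbs_of_reaction(7.1, as.numeric(q_of(gly$tpi)), 298.15)
  dg_gapdh <- gibbs_of_reaction(51.5, as.numeric(q_of(gly$gapdh)), 298.15)
  dg_comp <- gibbs_of_reaction(7.1 + 51.5, as.numeric(q_of(comp)), 298.15)
  expect_equal(dg_tpi + dg_gapdh, dg_comp, tolerance = 1e-6)
})

test_that("compare_modes pairs the two approaches on identical conditions", {
  cmpr <- compare_modes(gly, reg$standard, condB, reg)
  expect_equal(nrow(cmpr), length(gly))
  expect_true(all(c("dRg", "dRg_c", "sign_disagrees") %in% names(cmpr)))
  # with every gamma* = 1 the two coincide: pure-water trace limit
  rngs <- lapply(gly$pgi$stoichiometry, function(n) list(min = 1e-9, max = 1e-8))
  cs <- condition_set("custom", 298.15, 7, metabolite_ranges = rngs,
                      mode = "activity")
  one <- compare_modes(gly["pgi"], reg$standard, cs, reg)
  expect_equal(one$dRg, one$dRg_c, tolerance = 1e-3)
})

test_that("autoplot produces ggplot objects for reports and comparisons", {
  tb <- run_tfa(gly[c("tpi", "gapdh")], reg$standard, condA, reg,
                mode = "concentration")
  expect_s3_class(ggplot2::autoplot(tb), "ggplot")
  cmpr <- compare_modes(gly[c("tpi", "pgam")], reg$standard, condB, reg)
  expect_s3_class(ggplot2::autoplot(cmpr), "ggplot")
})
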