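typed_df <- function(types, city = "A") {
  data.frame(city = city, year = seq_along(types) + 2000, type = types,
             stringsAsFactors = FALSE)
}

test_that("quantile typing cuts the pooled sample into balanced bins", {
  df <- data.frame(city = letters[1:8], year = 2001, etotal = 1:8)
  t4 <- classify_levels(df, K = 4)
  expect_equal(t4$type, c(1, 1, 2, 2, 3, 3, 4, 4))

  t2 <- classify_levels(df, K = 2)
  expect_equal(t2$type, rep(1:2, each = 4))

  # rank-based: any monotone transformation leaves types unchanged
  df_exp <- df; df_exp$etotal <- exp(df$etotal)
  expect_equal(classify_levels(df_exp, K = 4)$type, t4$type)

  # bin occupancy between floor(N/K) and ceil(N/K) for distinct values
  set.seed(5)
  df_rand <- data.frame(city = sprintf("c%02d", 1:18),
                        year = rep(2001:2003, each = 6),
                        etotal = runif(18))
  occ <- table(classify_levels(df_rand, K = 4)$type)
  expect_true(all(occ >= floor(18 / 4) & occ <= ceiling(18 / 4)))

  expect_error(classify_levels(data.frame(city = "a", year = 1, etotal = 1),
                               K = 4),
               class = "herdghg_validation_error")
})

test_that("transition counts and MLE probabilities match hand enumeration", {
  m <- transition_matrix(typed_df(c(1, 1, 2, 1, 1)), K = 2)
  expect_equal(m$counts, matrix(c(2L, 1L, 1L, 0L), 2, byrow = TRUE,
                                dimnames = dimnames(m$counts)))
  expect_equal(unname(m$probs), matrix(c(2 / 3, 1 / 3, 1, 0), 2, byrow = TRUE))

  const <- transition_matrix(typed_df(rep(2, 5)), K = 3)
  expect_equal(unname(const$probs[2, ]), c(0, 1, 0))
  expect_true(all(const$zero_rows[c(1, 3)]))
  expect_equal(unname(const$probs[1, ]), c(0, 0, 0))

  # conservation: counts sum to n_cities x (n_years - lag)
  g <- generate_typed_sequences(matrix(0.25, 4, 4), n_units = 7, n_years = 9,
                                seed = 2)
  expect_equal(sum(transition_matrix(g)$counts), 7 * 8)
})

test_that("the estimator recovers a known generator within sampling error", {
  P <- matrix(c(0.70, 0.20, 0.07, 0.03,
                0.15, 0.60, 0.20, 0.05,
                0.05, 0.25, 0.55, 0.15,
                0.02, 0.08, 0.20, 0.70), 4, 4, byrow = TRUE)
  typed <- generate_typed_sequences(P, n_units = 100, n_years = 300, seed = 11)
  est <- transition_matrix(typed)
  expect_lt(max(rowSums(abs(est$probs - P))), 0.05)

  # identity chain: every sequence constant
  id <- generate_typed_sequences(diag(3), n_units = 5, n_years = 10, seed = 1)
  expect_true(all(tapply(id$type, id$city, function(x) length(unique(x))) == 1))

  # determinism under a fixed seed; sensitivity to the seed
  a <- generate_typed_sequences(P, 10, 20, seed = 4)
  b <- generate_typed_sequences(P, 10, 20, seed = 4)
  expect_identical(a, b)
  expect_false(identical(a, generate_typed_sequences(P, 10, 20, seed = 5)))

  expect_error(generate_typed_sequences(matrix(1, 2, 2), 5, 5),
               class = "herdghg_validation_error")
})

test_that("spatial lag averages neighbours and bins on the shared thresholds", {
  ring4 <- generate_adjacency(c("a", "b", "c", "d"), "ring")
  df <- data.frame(city = c("a", "b", "c", "d"), year = 2001,
                   etotal = c(0, 10, 0, 10))
  # in a 4-cycle each city's two neighbours carry the opposite value
  lag <- spatial_lag_class(df, ring4, thresholds = c(2.5, 5, 7.5))
  expect_equal(lag$lag_value, c(10, 0, 10, 0))
  expect_equal(lag$lag_class, c(4, 1, 4, 1))
  # a value sitting exactly on a threshold falls in the upper (lower-closed) bin
  df5 <- data.frame(city = c("a", "b", "c", "d"), year = 2001,
                    etotal = c(5, 5, 5, 5))
  expect_equal(spatial_lag_class(df5, ring4,
                                 thresholds = c(2.5, 5, 7.5))$lag_class,
               rep(3, 4))

  # all neighbours share value v: lag class equals class(v)
  df2 <- data.frame(city = c("a", "b", "c", "d"), year = 2001,
                    etotal = c(8, 8, 8, 8))
  lag2 <- spatial_lag_class(df2, ring4, thresholds = c(2.5, 5, 7.5))
  expect_equal(lag2$lag_class,
               rep(herdghg:::bin_by_thresholds(8, c(2.5, 5, 7.5)), 4))

  iso <- list(a = "b", b = "a", c = character(0))
  df3 <- data.frame(city = c("a", "b", "c"), year = 2001, etotal = 1:3)
  expect_error(spatial_lag_class(df3, iso, 1.5),
               class = "herdghg_validation_error")
})

test_that("stratified transition counts conserve the conventional counts", {
  set.seed(21)
  P <- matrix(c(0.8, 0.2, 0.3, 0.7), 2, 2, byrow = TRUE)
  typed <- generate_typed_sequences(P, n_units = 12, n_years = 15, seed = 8)
  # arbitrary lag classes, independent of the dynamics
  lags <- typed[c("city", "year")]
  lags$lag_class <- 1 + (seq_len(nrow(lags)) %% 2)
  conv <- transition_matrix(typed)
  strata <- spatial_transition_matrices(typed, lags, K = 2)
  expect_equal(Reduce(`+`, lapply(strata, `[[`, "counts")), conv$counts)

  # constant lag class: that stratum is the conventional matrix, others empty
  lags$lag_class <- 2
  strata2 <- spatial_transition_matrices(typed, lags, K = 2)
  expect_equal(strata2[["2"]]$probs, conv$probs)
  expect_equal(sum(strata2[["1"]]$counts), 0)
  expect_true(all(strata2[["1"]]$zero_rows))
})

test_that("neighbour-independent dynamics give equal stratum matrices", {
  P <- matrix(c(0.70, 0.20, 0.07, 0.03,
                0.15, 0.60, 0.20, 0.05,
                0.05, 0.25, 0.55, 0.15,
                0.02, 0.08, 0.20, 0.70), 4, 4, byrow = TRUE)
  typed <- generate_typed_sequences(P, n_units = 200, n_years = 200, seed = 31)
  units <- sprintf("U%04d", 1:200)
  ring <- generate_adjacency(units, "ring")
  lags <- spatial_lag_class(typed, ring, thresholds = c(1.5, 2.5, 3.5),
                            value = "type")
  strata <- spatial_transition_matrices(typed, lags)
  conv <- transition_matrix(typed)
  # compare rows estimated from enough transitions for the L1 sampling
  # error of a 4-entry multinomial row to sit well below 0.1
  compared <- 0
  for (g in names(strata)) {
    for (i in which(strata[[g]]$row_totals >= 1000)) {
      expect_lt(sum(abs(strata[[g]]$probs[i, ] - conv$probs[i, ])), 0.1)
      compared <- compared + 1
    }
  }
  expect_gt(compared, 0)
})

test_that("self-locking range matches the published matrix diagonal", {
  expect_equal(unname(diagonal_summary(published_markov())),
               c(0.6712, 0.8947))
  expect_equal(unname(diagonal_summary(diag(4))), c(1, 1))
  expect_equal(unname(diagonal_summary(matrix(0.25, 4, 4))), c(0.25, 0.25))
  empty <- transition_matrix(typed_df(c(1, 1)), K = 2)
  empty$zero_rows[] <- TRUE
  expect_error(diagonal_summary(empty), class = "herdghg_domain_error")
})
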