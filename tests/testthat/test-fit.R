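# End-to-end model fitting: sanity, determinism, masking audit, methods.

test_that("training keeps a finite loss trace and reduces the loss", {
  sd <- generate_dataset(synthetic_spec(n_microbes = 40, n_drugs = 80,
                                        target_density = 0.08, seed = 2))
  cfg <- mda_config(embed_dim = 16, n_heads = 2, epochs = 30, knn_k = 5,
                    ko_c = 4, learning_rate = 1e-3, seed = 9)
  fit <- hypermda(sd$ds, sd$ms1, sd$ds1, cfg)
  expect_true(all(is.finite(fit$loss_trace)))
  expect_lt(fit$loss_trace[30], fit$loss_trace[1])
})

test_that("identical seed and config reproduce identical losses", {
  sd <- tiny_synth()
  cfg <- tiny_config()
  f1 <- hypermda(sd$ds, sd$ms1, sd$ds1, cfg)
  f2 <- hypermda(sd$ds, sd$ms1, sd$ds1, cfg)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$scores, f2$scores)
})

test_that("held-out labels cannot influence training (masking audit)", {
  sd <- tiny_synth()
  cfg <- tiny_config()
  pos <- which(sd$ds$A == 1, arr.ind = TRUE)
  neg <- which(sd$ds$A == 0, arr.ind = TRUE)
  held <- rbind(pos[1:4, ], neg[1:4, ])
  f1 <- hypermda(sd$ds, sd$ms1, sd$ds1, cfg, exclude = held)
  # flip every held-out label; nothing in training may change
  A2 <- sd$ds$A
  A2[held] <- 1 - A2[held]
  ds2 <- mda_dataset(A2, sd$ds$microbe_ids, sd$ds$drug_ids)
  f2 <- hypermda(ds2, sd$ms1, sd$ds1, cfg, exclude = held)
  expect_identical(f1$loss_trace, f2$loss_trace)
  expect_identical(f1$scores, f2$scores)
})

test_that("predict extracts scores consistently and validates indices", {
  sd <- tiny_synth()
  fit <- hypermda(sd$ds, sd$ms1, sd$ds1, tiny_config())
  S <- predict(fit)
  pairs <- expand.grid(i = 1:3, j = 1:4)
  sc <- predict(fit, pairs)
  expect_length(sc, 12)
  expect_equal(sc, S[as.matrix(pairs)])
  # identifier-based lookup agrees with index-based lookup
  byid <- predict(fit, data.frame(m = sd$ds$microbe_ids[2], d = sd$ds$drug_ids[5]))
  expect_equal(byid, S[2, 5])
  # ranking is invariant under a strictly increasing transform
  expect_equal(order(-sc), order(-(1 / (1 + exp(-sc)))))
  expect_error(predict(fit, cbind(999, 1)), "out of range")
  resp <- predict(fit, pairs, type = "response")
  expect_true(all(resp > 0 & resp < 1))
})

test_that("model methods expose the fit the standard way", {
  sd <- tiny_synth()
  fit <- hypermda(sd$ds, sd$ms1, sd$ds1, tiny_config())
  expect_output(print(fit), "Dual-hypergraph")
  expect_output(print(summary(fit)), "Final losses")
  expect_named(coef(fit), c("enc_m1", "enc_m2", "enc_d1", "enc_d2",
                            "head_m", "head_d", "int_m", "int_d"))
  expect_equal(dim(fitted(fit)), dim(sd$ds$A))
  expect_true(all(fitted(fit) > 0 & fitted(fit) < 1))
  r <- residuals(fit)
  expect_equal(dim(r), dim(sd$ds$A))
  sims <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_true(all(sims[[1]] %in% 0:1))
  expect_identical(sims, simulate(fit, nsim = 2, seed = 1))
  rk <- rank_candidates(fit, drug = sd$ds$drug_ids[1], n = 5)
  expect_equal(nrow(rk), 5)
  expect_true(!is.unsorted(rev(rk$score)))
})

test_that("single-view and linear-fusion pipelines run and differ", {
  sd <- tiny_synth()
  cfg <- tiny_config(epochs = 2)
  # interaction-profile kernels only (no external similarity needed)
  f_gip <- hypermda(sd$ds, config = ablate(cfg, "MS2DS2"))
  expect_true(all(is.finite(f_gip$loss_trace)))
  # linear fusion differs from non-linear fusion on the same views
  c_lin <- ablate(cfg, "Linear")
  cache_lin <- hypermda:::build_model_cache(sd$ds, sd$ms1, sd$ds1, c_lin)
  cache_snf <- hypermda:::build_model_cache(sd$ds, sd$ms1, sd$ds1, cfg)
  expect_gt(max(abs(cache_lin$fused_m$S_final - cache_snf$fused_m$S_final)),
            1e-4)
  # external-only uses ms1/ds1 verbatim (symmetrized), not the kernels
  c_ext <- ablate(cfg, "MS1DS1")
  cache_ext <- hypermda:::build_model_cache(sd$ds, sd$ms1, sd$ds1, c_ext)
  expect_equal(cache_ext$fused_m$S_final, (sd$ms1 + t(sd$ms1)) / 2)
  expect_error(hypermda:::build_model_cache(sd$ds, NULL, NULL, c_ext),
               "external")
})
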