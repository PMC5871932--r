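test_that("truncation selection ranks by value then id, and handles mortality", {
  idx <- data.frame(individual_id = c("d", "b", "a", "c"),
                    value = c(3, 5, 5, 1))
  expect_equal(rank_by_index(idx), c("a", "b", "d", "c"))
  # all-equal predictions fall back to id order
  idx$value <- 0
  expect_equal(rank_by_index(idx), c("a", "b", "c", "d"))

  ranked <- sprintf("p%02d", 1:30)
  expect_equal(apply_mortality(ranked, 12), ranked[1:12])
  # 9 of the top 12 dead: 3 surviving top plants + the next 9 ranked
  deaths <- ranked[c(1:9)]
  expect_equal(apply_mortality(ranked, 12, deaths), ranked[10:21])
  # every top-n plant dead: ranks n+1..2n
  expect_equal(apply_mortality(ranked, 12, ranked[1:12]), ranked[13:24])
  expect_error(apply_mortality(ranked, 12, ranked[1:20]), "fewer survivors")
  expect_error(apply_mortality(c("a", "a", "b"), 2), "duplicate")
})

test_that("selection overlap counts match the hypergeometric expectation", {
  expect_equal(selection_overlap(letters[1:5], letters[1:5], 3), 3L)
  expect_equal(selection_overlap(letters[1:5], letters[6:10], 5), 0L)
  expect_error(selection_overlap(c("a", "a"), c("a", "b"), 2), "duplicate")
  expect_error(selection_overlap(letters[1:3], letters[1:3], 5), "exceeds")

  set.seed(1)
  ids <- sprintf("x%03d", 1:192)
  ov <- replicate(1000, selection_overlap(sample(ids), sample(ids), 12))
  expect_lt(abs(mean(ov) - 12^2 / 192), 0.2)
})

test_that("marker panels lose only monomorphic markers", {
  g <- cbind(a = c(0L, 1L, 2L), b = c(2L, 2L, 2L), c = c(0L, 0L, 1L))
  expect_equal(update_marker_panel(c("a", "b", "c"), g), c("a", "c"))
  expect_equal(update_marker_panel(c("a", "c"), g), c("a", "c"))
  expect_error(update_marker_panel("b", g), "no polymorphic")
})

test_that("offspring haplotypes are mosaics of the recorded parents", {
  set.seed(2)
  map <- tiny_map(40, 2)
  pop <- simulate_founders(10, map)
  off <- random_mate(pop, 25)
  for (i in seq_len(25)) {
    d <- match(off$dam[i], pop$id)
    s <- match(off$sire[i], pop$id)
    expect_true(all(off$hap1[i, ] == pop$hap1[d, ] |
                      off$hap1[i, ] == pop$hap2[d, ]))
    expect_true(all(off$hap2[i, ] == pop$hap1[s, ] |
                      off$hap2[i, ] == pop$hap2[s, ]))
  }
})

test_that("GS cycle 1 selects seed parents after pollination by the whole population", {
  set.seed(3)
  w <- setup_experiment(n_markers = 150, n_lg = 2, n_qtl = 40,
                        n_founders = 80, seed = 3)
  cfg <- scheme_config("gs", years = 1, gs_cycle1_size = 60,
                       gs_cycle2_size = 30, n_selected = 6,
                       bottleneck_k = 20, seed_stock_n = 10, seed = 3)
  ini <- bottleneck_then_expand(w$founders, 20, 60, seed = 4)
  c1 <- run_gs_cycle1(ini, w$arch, w$index_model, cfg, cycle_label = "GS1")
  expect_identical(c1$record$pollen_parent_ids, ini$id)
  expect_length(c1$record$selected_ids, 6L)
  # the selected set is exactly the top of the expected-index ranking
  expect_identical(c1$record$selected_ids, rank_by_index(c1$index)[1:6])
  expect_true(all(c1$offspring$dam %in% c1$record$selected_ids))
  # sires come from the whole population, not only the selected set
  expect_true(any(!c1$offspring$sire %in% c1$record$selected_ids))
  expect_equal(pop_size(c1$offspring), 30L)
  expect_error(run_gs_cycle1(c1$offspring, w$arch, w$index_model, cfg),
               "gs_cycle1_size")

  # cycle 2: both parents from the selected set, before pollination
  c2 <- run_gs_cycle2(c1$offspring, c1$models, w$index_model, cfg,
                      panel = c1$panel, cycle_label = "GS2")
  expect_identical(c2$record$pollen_parent_ids, c2$record$seed_parent_ids)
  expect_true(all(c2$offspring$dam %in% c2$record$selected_ids) &&
                all(c2$offspring$sire %in% c2$record$selected_ids))
  expect_equal(pop_size(c2$offspring), 60L)
})

test_that("PS selects the truly best plants when the index is noiseless", {
  set.seed(5)
  map <- tiny_map(120, 2)
  founders <- simulate_founders(80, map)
  corr <- field_trait_correlations()
  arch <- build_trait_architecture(map, corr, h2 = 1, n_qtl = 40,
                                   ref_pop = founders)
  imod <- buckwheat_index_model()
  cfg <- scheme_config("ps", years = 1, ps_size = 60, n_selected = 6,
                       bottleneck_k = 20, seed_stock_n = 10, seed = 5)
  ini <- bottleneck_then_expand(founders, 20, 60, seed = 6)
  cy <- run_ps_cycle(ini, arch, imod, cfg)
  truth <- compute_index(genetic_values(ini, arch), imod)
  expect_setequal(cy$record$selected_ids, rank_by_index(truth)[1:6])
  expect_equal(cy$record$selection_source, "observed")
})

test_that("selection with a random index gives no systematic gain", {
  set.seed(6)
  w <- setup_experiment(n_markers = 120, n_lg = 2, n_qtl = 40,
                        n_founders = 80, seed = 6)
  ini <- bottleneck_then_expand(w$founders, 30, 96, seed = 7)
  base <- true_index_mean(ini, w$arch, w$index_model)
  resp <- replicate(60, {
    sel <- sample(ini$id, 12)
    off <- random_mate(ini, 60, dams = sel)
    true_index_mean(off, w$arch, w$index_model) - base
  })
  tt <- stats::t.test(resp)
  expect_gt(tt$p.value, 0.01)
})

test_that("a full program is labelled, sized, and bit-reproducible", {
  w <- setup_experiment(n_markers = 120, n_lg = 2, n_qtl = 30,
                        n_founders = 60, seed = 8)
  cfg <- scheme_config("gs", years = 3, gs_cycle1_size = 48,
                       gs_cycle2_size = 24, n_selected = 6,
                       bottleneck_k = 20, seed_stock_n = 8, seed = 9)
  p1 <- run_program(cfg, w$arch, w$index_model, w$founders)
  expect_equal(names(p1$records), paste0("GS", 1:6))
  expect_equal(names(p1$models), c("GS1", "GS3", "GS5"))
  expect_true(all(diff(p1$panel_sizes) <= 0))
  expect_equal(pop_size(p1$populations$post_gs6), 48L)
  expect_equal(vapply(p1$stock_phenotypes[-1], nrow, 1L),
               c(post_gs1 = 8L, post_gs2 = 8L, post_gs3 = 8L, post_gs4 = 8L,
                 post_gs5 = 8L, post_gs6 = 8L))

  p2 <- run_program(cfg, w$arch, w$index_model, w$founders)
  expect_identical(p1$populations$post_gs6$hap1, p2$populations$post_gs6$hap1)
  expect_identical(lapply(p1$records, `[[`, "selected_ids"),
                   lapply(p2$records, `[[`, "selected_ids"))
  expect_identical(p1$stock_phenotypes, p2$stock_phenotypes)

  cfg_ps <- scheme_config("ps", years = 2, ps_size = 48, n_selected = 6,
                          bottleneck_k = 20, seed_stock_n = 8, seed = 9)
  pp <- run_program(cfg_ps, w$arch, w$index_model, w$founders)
  expect_equal(names(pp$records), c("PS1", "PS2"))
})

test_that("mortality removes plants from the selected set", {
  set.seed(10)
  w <- setup_experiment(n_markers = 100, n_lg = 2, n_qtl = 30,
                        n_founders = 60, seed = 10)
  cfg <- scheme_config("ps", years = 1, ps_size = 48, n_selected = 6,
                       bottleneck_k = 20, mortality_rate = 0.3,
                       seed_stock_n = 8, seed = 10)
  ini <- bottleneck_then_expand(w$founders, 20, 48, seed = 11)
  cy <- run_ps_cycle(ini, w$arch, w$index_model, cfg)
  expect_gt(length(cy$record$deaths), 0)
  expect_false(any(cy$record$selected_ids %in% cy$record$deaths))
})
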