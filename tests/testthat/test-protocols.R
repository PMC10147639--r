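test_that("learning schedule has the three-phase shape", {
  groups <- list(1:40, 41:80)
  set.seed(1)
  sch <- build_learning_schedule(groups, block_len = 20, n_blocks = 10,
                                 rest_before = 200, rest_after = 500)
  expect_s3_class(sch, "stimulus_schedule")
  expect_equal(nrow(sch$blocks), 10)
  expect_equal(min(sch$blocks$t_start), 200)
  expect_equal(max(sch$blocks$t_end), 200 + 10 * 20)
  expect_equal(sch$total_duration, 200 + 200 + 500)
  expect_true(all(sch$blocks$amplitude == 3))
  expect_true(all(sch$blocks$t_end - sch$blocks$t_start == 20))

  # zero blocks: pure rest
  sch0 <- build_learning_schedule(groups, n_blocks = 0, rest_before = 10,
                                  rest_after = 20)
  expect_equal(nrow(sch0$blocks), 0)
  expect_equal(sch0$total_duration, 30)

  # strict alternation cycles the groups in order with gaps
  scha <- build_learning_schedule(groups, block_len = 20, n_blocks = 4,
                                  gap = 5, strict_alternation = TRUE,
                                  rest_before = 0, rest_after = 0)
  expect_equal(vapply(scha$blocks$targets, min, 1L), c(1L, 41L, 1L, 41L))
  expect_equal(diff(scha$blocks$t_start), rep(25, 3))

  expect_error(build_learning_schedule(list(1:3, integer(0))), "non-empty")
})

test_that("schedules never target inhibitory neurons in a simulation", {
  set.seed(4)
  st <- init_network(20, 5, "ei")
  bad <- build_learning_schedule(list(14:17), n_blocks = 2, rest_before = 0,
                                 rest_after = 0)
  expect_error(simulate_network(st, 1, rule = plasticity_rule(dale_mode = "ei"),
                                schedule = bad),
               "inhibitory")
})

test_that("pre-trained matrices encode the feedforward E-I architecture", {
  lay <- layout_modules(100, 2, 20)
  w <- build_pretrained_matrix(100, lay)
  expect_true(all(w %in% c(-1, 0, 1)))
  expect_true(all(diag(w) == 0))
  c1 <- lay$clusters[[1]]; c2 <- lay$clusters[[2]]
  i1 <- lay$inhibitory[lay$inhibitory_assignment == 1]
  i2 <- lay$inhibitory[lay$inhibitory_assignment == 2]
  off <- function(m) m[row(m) != col(m)]
  expect_true(all(off(w[c1, c1]) == 1))
  expect_true(all(w[c1, c2] == 0))
  expect_true(all(w[i1, c1] == 1))
  expect_true(all(w[i1, c2] == 0))
  expect_true(all(w[c2, i1] == -1))
  expect_true(all(w[c1, i1] == 0))
  expect_true(all(w[i2, i1] == -1))
  expect_true(all(off(w[i1, i1]) == 0))

  # Dale sign constraints by column
  types <- rep(c("excitatory", "inhibitory"), c(80, 20))
  expect_true(all(w[, types == "excitatory"] >= 0))
  expect_true(all(w[, types == "inhibitory"] <= 0))

  # single cluster: all-to-all excitation, no inhibition targets
  lay1 <- layout_modules(10, 1, 2)
  w1 <- build_pretrained_matrix(10, lay1)
  expect_true(all(off(w1[1:8, 1:8]) == 1))
  expect_true(all(w1[1:8, 9:10] == 0))

  # splay construction: N/2 clusters of one excitatory + one inhibitory
  layS <- layout_modules(20, 10, 10)
  wS <- build_pretrained_matrix(20, layS)
  expect_true(all(diag(wS[11:20, 1:10]) == 1))  # E_k -> I_k
  expect_equal(sum(wS[1:10, 11:20] == -1), 10 * 9)  # I_k inhibits others

  expect_error(module_layout(list(1:5), 6:7, c(1, 3), 7), "nonexistent")
})

test_that("hub layouts wire hubs into both clusters without inhibition", {
  lay <- layout_hubs(100, 8, 17)
  expect_equal(length(lay$hubs), 8)
  w <- build_pretrained_matrix(100, lay)
  hubs <- lay$hubs
  excl1 <- setdiff(lay$clusters[[1]], hubs)
  excl2 <- setdiff(lay$clusters[[2]], hubs)
  # hubs excite and are excited by both clusters
  expect_true(all(w[excl1, hubs] == 1))
  expect_true(all(w[excl2, hubs] == 1))
  # hubs excite the inhibitory neurons of both clusters
  expect_true(all(w[lay$inhibitory, hubs] == 1))
  # hubs receive no inhibition
  expect_true(all(w[hubs, lay$inhibitory] == 0))
  # exclusive members are inhibited by the other cluster only
  i1 <- lay$inhibitory[lay$inhibitory_assignment == 1]
  expect_true(all(w[excl2, i1] == -1))
  expect_true(all(w[excl1, i1] == 0))
})

test_that("softening keeps signs and maps saturated/pruned levels", {
  lay <- layout_modules(30, 2, 4)
  types <- rep(c("excitatory", "inhibitory"), c(26, 4))
  w <- soften_pretrained(build_pretrained_matrix(30, lay), types,
                         w_high = 0.9, w_low = 0.05)
  off <- row(w) != col(w)
  expect_true(all(abs(w[off]) %in% c(0.05, 0.9)))
  expect_true(all(w[, 1:26][row(w[, 1:26]) != col(w[, 1:26])] > 0))
  expect_true(all(w[, 27:30] < 0 | row(w[, 27:30]) == col(w[, 27:30]) + 26))
  expect_true(all(diag(w) == 0))
})

test_that("scrambling only touches the excitatory block", {
  set.seed(21)
  st <- init_network(100, 20, "ei")
  st$weights[1:80, 1:80] <- 0.9
  diag(st$weights) <- 0
  set.seed(33)
  s1 <- scramble_excitatory_weights(st)
  set.seed(33)
  s2 <- scramble_excitatory_weights(st)
  expect_identical(s1$weights, s2$weights)
  expect_identical(s1$weights[, 81:100], st$weights[, 81:100])
  expect_identical(s1$weights[81:100, ], st$weights[81:100, ])
  ee <- s1$weights[1:80, 1:80][row(diag(80)) != col(diag(80))]
  expect_lt(abs(mean(ee) - 0.5), 3 * sd(ee) / sqrt(length(ee)))
  expect_true(all(diag(s1$weights) == 0))
})

test_that("stimulus groups split excitatory indices as in the protocols", {
  g <- stimulus_groups(80, 2)
  expect_equal(g[[1]], 1:40)
  expect_equal(g[[2]], 41:80)
  g3 <- stimulus_groups(80, 3)
  expect_equal(lengths(g3), c(27, 27, 26))
  expect_equal(sort(unlist(g3)), 1:80)
  gh <- stimulus_groups(80, 2, n_hubs = 8)
  expect_equal(length(intersect(gh[[1]], gh[[2]])), 8)
  expect_equal(sort(unique(unlist(gh))), 1:80)
})
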