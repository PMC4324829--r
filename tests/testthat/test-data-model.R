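test_that("embedded fixture reproduces every printed colony and caste total", {
  fx <- table1_fixture()

  expect_equal(sum(fx$n_tested), 555L)
  expect_equal(sum(fx$n_infected), 276L)

  totals <- list(
    T7 = c(21, 27), T16 = c(28, 37), T42 = c(35, 57), T5 = c(5, 25),
    T26 = c(5, 24), T34 = c(39, 50), T37 = c(4, 42), T38 = c(17, 48),
    T17 = c(16, 19), T24 = c(26, 49), T31 = c(32, 55), T45 = c(9, 20),
    T46 = c(8, 33), TX = c(19, 42), TD1 = c(12, 27))
  for (colony in names(totals)) {
    d <- fx[fx$colony == colony, ]
    expect_equal(c(sum(d$n_infected), sum(d$n_tested)), totals[[colony]],
                 info = colony)
  }

  pooled <- function(stage) {
    d <- fx[fx$stage == stage, ]
    c(sum(d$n_infected), sum(d$n_tested))
  }
  expect_equal(pooled("queen"), c(13, 13))
  expect_equal(pooled("king"), c(5, 7))
  expect_equal(pooled("larva"), c(90, 144))
  expect_equal(pooled("worker"), c(55, 169))
  expect_equal(pooled("white_soldier"), c(57, 77))
  expect_equal(pooled("soldier"), c(56, 145))
})

test_that("colony CSV round-trips losslessly and validation names bad rows", {
  fx <- table1_fixture()
  path <- withr::local_tempfile(fileext = ".csv")
  write_colony_csv(fx, path)
  back <- load_colony_csv(path)
  expect_equal(back[names(back)], fx[names(back)], ignore_attr = TRUE)

  # label or ordinal stages both parse; reconstructed larva cell of T7
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,colony,stage,n_tested,n_infected",
               "A,T7,larva,6,5", "A,T8,2,6,5"), p2)
  d <- load_colony_csv(p2)
  expect_equal(d$stage, c("larva", "larva"))
  expect_equal(d$n_infected, c(5L, 5L))

  # empty cells are dropped with a warning
  p3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("species,colony,stage,n_tested,n_infected",
               "A,T7,larva,6,5", "A,T7,worker,0,0"), p3)
  expect_warning(d3 <- load_colony_csv(p3), "n_tested = 0")
  expect_equal(nrow(d3), 1L)

  # impossible counts, unknown labels, duplicates: errors naming the row
  bad <- function(lines) {
    p <- tempfile(fileext = ".csv")
    writeLines(c("species,colony,stage,n_tested,n_infected", lines), p)
    p
  }
  expect_error(load_colony_csv(bad("A,T7,larva,6,7")), "row 1")
  expect_error(load_colony_csv(bad("E,T7,larva,6,5")), "species")
  expect_error(load_colony_csv(bad("A,T7,grub,6,5")), "stage")
  expect_error(load_colony_csv(bad(c("A,T7,larva,6,5", "A,T7,larva,4,1"))),
               "duplicate")
})

test_that("pooling sums exactly and omits cells absent from every colony", {
  fx <- table1_fixture()
  sp <- pool(fx, "by_species_stage")

  # hand-sum of the six species-C worker cells: 16+10+9+3+10+10 tested,
  # 14+3+1+0+0+1 infected
  cw <- sp[sp$species == "C" & sp$stage == "worker", ]
  expect_equal(c(cw$n, cw$k), c(58, 19))

  ws <- sp[sp$stage == "white_soldier", ]
  expect_equal(c(sum(ws$n), sum(ws$k)), c(77, 57))

  # species D has no larvae: the cell must be absent, not zero
  expect_false(any(sp$species == "D" & sp$stage == "larva"))

  # by-colony pooling of a one-colony dataset is the identity
  one <- fx[fx$colony == "T7", ]
  bc <- pool(one, "by_colony_stage")
  expect_equal(bc$n, one$n_tested[one$stage_ordinal %in% 2:5])
  expect_equal(bc$k, one$n_infected[one$stage_ordinal %in% 2:5])

  expect_error(pool(fx[0, ]), "empty")
})
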