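test_that("free-energy bookkeeping is unit-consistent", {
  set.seed(3)
  pr <- random_pair_set(50)
  cond <- thermo_conditions(57)
  en <- duplex_energy(pr$a, pr$b, cond)
  tk <- 57 + 273.15
  expect_equal(en$delta_G_at_T, en$delta_H - tk * en$delta_S / 1000,
               tolerance = 1e-12)
  bound <- en$n_pairs > 0
  expect_equal(en$K_eq[bound],
               exp(-en$delta_G_at_T[bound] / (1.9872e-3 * tk)),
               tolerance = 1e-12)
  expect_true(all(en$K_eq[!bound] == 0))
})

test_that("closed-form equilibrium matches a bisection solver", {
  set.seed(8)
  pr <- random_pair_set(300)
  cond <- thermo_conditions(57)
  y <- builtin_yield(pr$a, pr$b, cond)
  en <- duplex_energy(pr$a, pr$b, cond)
  for (i in seq_len(nrow(y))) {
    x_ref <- oracle_equilibrium(en$K_eq[i], 1e-6, 1e-6,
                                homodimer = pr$a[i] == pr$b[i])
    expect_lt(abs(y$yield_fraction[i] - x_ref / 1e-6), 1e-10)
  }
  # homodimer branch explicitly
  s <- "CCATGGAGGCGCGCCTTT"
  yh <- builtin_yield(s, s, cond)
  enh <- duplex_energy(s, s, cond)
  xh <- oracle_equilibrium(enh$K_eq, 1e-6, homodimer = TRUE)
  expect_lt(abs(yh$yield_fraction - xh / 1e-6), 1e-10)
})

test_that("mass is conserved at every returned equilibrium", {
  set.seed(9)
  pr <- random_pair_set(200)
  y <- builtin_yield(pr$a, pr$b)
  homo <- pr$a == pr$b
  strand_total <- ifelse(homo, y$monomer_a + 2 * y$duplex_concentration,
                         y$monomer_a + y$duplex_concentration)
  expect_true(all(abs(strand_total - 1e-6) / 1e-6 < 1e-9))
})

test_that("limiting cases of the two-state model are exact", {
  # delta-G = 0 gives K = 1 and the small-K limit x ~ K a0 b0
  x <- duplexr:::hetero_duplex_conc(1, 1e-6, 1e-6)
  expect_equal(x, 1e-12, tolerance = 1e-5)
  expect_equal(x / 1e-6, 1e-6, tolerance = 1e-5)
  # saturation: K -> Inf drives the yield to exactly 1
  expect_equal(duplexr:::hetero_duplex_conc(1e30, 1e-6, 1e-6) / 1e-6, 1,
               tolerance = 1e-9)
  # homodimer saturation consumes all strands into duplex (yield 1/2)
  expect_equal(duplexr:::homo_duplex_conc(1e30, 1e-6) / 1e-6, 0.5,
               tolerance = 1e-9)
})

test_that("perfect complements hybridise near-completely and monotonely in T", {
  set.seed(10)
  for (rep in 1:20) {
    s <- random_sequence(20)
    y37 <- builtin_yield(s, reverse_complement(s), thermo_conditions(37))
    expect_gt(y37$yield_fraction, 0.99)
    prof <- yield_profile(s, reverse_complement(s),
                          temps = seq(30, 80, by = 2.5))
    expect_true(all(diff(prof$yield_fraction) <= 1e-12))
  }
})

test_that("yield is invariant under strand swap and joint reverse complement", {
  set.seed(12)
  pr <- random_pair_set(60)
  y1 <- builtin_yield(pr$a, pr$b)$yield_fraction
  y2 <- builtin_yield(pr$b, pr$a)$yield_fraction
  y3 <- builtin_yield(reverse_complement(pr$a),
                      reverse_complement(pr$b))$yield_fraction
  expect_equal(y1, y2, tolerance = 1e-9)
  expect_equal(y1, y3, tolerance = 1e-9)
})

test_that("non-complementary strands give negligible yield", {
  a <- "ATATTATAATATTATATTAT"
  b <- "ATTATAATATATTATAATAT" # same-sense A/T strand, no C/G anywhere
  y <- builtin_yield(a, b, thermo_conditions(57))
  expect_lt(y$yield_fraction, 0.1)
})

test_that("yield profiles are deterministic and validate inputs", {
  s <- random_sequence(20, rng_seed = 5)
  p1 <- yield_profile(s, reverse_complement(s), temps = c(42, 42))
  expect_equal(p1$yield_fraction[1], p1$yield_fraction[2])
  expect_error(yield_profile(s, s, temps = numeric(0)), "non-empty")
  expect_error(thermo_conditions(120), "temperature")
  expect_error(thermo_conditions(57, initial_concentration = 0), "> 0")
})

test_that("the self-complementary worked example favours the homodimer", {
  # an 18-mer containing an 8-bp self-complementary core: its duplex should
  # dominate the single-stranded form at 1 uM
  s <- "CCATGGAGGCGCGCCTTT"
  y <- builtin_yield(s, s, thermo_conditions(37))
  expect_gt(y$duplex_concentration / y$monomer_a, 5)
})

test_that("NUPACK input files and output parsing follow the v3 dialect", {
  prefix <- tempfile("nup")
  write_nupack_input("ACGTACGT", "TTTTACGT", prefix, 1e-6)
  inp <- readLines(paste0(prefix, ".in"))
  expect_identical(inp[1], "2")
  expect_identical(inp[2:3], c("ACGTACGT", "TTTTACGT"))
  expect_identical(inp[4], "2") # max complex size
  con <- readLines(paste0(prefix, ".con"))
  expect_length(con, 2L)
  expect_equal(as.numeric(con), rep(1e-6, 2))
  # homodimer systems list the strand once
  write_nupack_input("ACGTACGT", "ACGTACGT", prefix)
  expect_identical(readLines(paste0(prefix, ".in"))[1], "1")

  eq <- tempfile(fileext = ".eq")
  writeLines(c("% NUPACK 3.2.2", "% complex  strands  energy  conc",
               "1\t1\t0\t-1.23e+00\t9.0e-07",
               "2\t0\t1\t-2.34e+00\t8.5e-07",
               "3\t1\t1\t-2.00e+01\t1.0e-07"), eq)
  tab <- parse_nupack_eq(eq, 2)
  expect_equal(nrow(tab), 3L)
  expect_equal(tab$concentration[tab$n1 == 1 & tab$n2 == 1], 1.0e-07)
  writeLines(c("% only comments"), eq)
  expect_error(parse_nupack_eq(eq, 2), "no complex rows")
})

test_that("a missing NUPACK installation raises a configuration error", {
  skip_if(nupack_available(), "NUPACK installed; error path not exercised")
  expect_error(nupack_yield("ACGTACGTACGTACGT", "ACGTACGTACGTACGT"),
               "not found on PATH")
})
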