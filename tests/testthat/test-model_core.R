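# Parameters, initial conditions, and the algebra of the right-hand side.

test_that("baseline parameters carry the literature values and capacity", {
  p <- baseline_parameters()
  expect_equal(p[["a"]], 0.43)
  expect_equal(p[["g1"]], 120)
  expect_equal(p[["k2"]], 2.97e-6)
  expect_equal(p[["l2"]], 0.5137)
  expect_equal(p[["l1"]], 2.97)
  expect_equal(p[["d0"]], 0)
  expect_lt(abs(1 / p[["b"]] - 9.80e8) / 9.80e8, 0.01)
  expect_error(validate_parameters(p[-1]), "missing parameter")
  p_bad <- p; p_bad[["h1"]] <- 0
  expect_error(validate_parameters(p_bad), "strictly positive.*h1")
})

test_that("initial conditions encode route, immune state, and dose", {
  iv <- baseline_initial_conditions("intravenous", "cold", 1e6, 1e6)
  expect_equal(iv[["S_B"]], 1e6)
  expect_equal(iv[["S_T"]], 0)
  expect_equal(iv[["I_C"]], 10)
  expect_equal(iv[["E_N"]], 100)
  expect_equal(unname(iv[c("T_I", "E_B", "E_T")]), c(0, 0, 0))
  expect_length(attr(iv, "param_overrides"), 0)

  it <- baseline_initial_conditions("intratumoral", "cold", 1e6, 1e6)
  expect_equal(it[["S_B"]], 0)
  expect_equal(it[["S_T"]], 1e6)

  hot <- baseline_initial_conditions("intravenous", "hot", 1e6, 1e6)
  expect_equal(hot[["I_C"]], 100)
  expect_equal(attr(hot, "param_overrides"), list(l2 = 0))

  # zero dose leaves every bacterial compartment empty (untreated system)
  none <- baseline_initial_conditions("intravenous", "cold", 1e6, 0)
  expect_equal(none[["S_B"]] + none[["S_T"]], 0)

  expect_error(baseline_initial_conditions(dose = -1), "dose")
  expect_error(baseline_initial_conditions(tumor_size = 0), "tumor_size")
})

test_that("overrides address parameters and ICs, rejecting unknown symbols", {
  p <- baseline_parameters()
  ic <- baseline_initial_conditions()
  r <- apply_overrides(p, ic, list(k1 = 5, S_B0 = 0, S_T0 = 1e6))
  expect_equal(r$params[["k1"]], 5)
  expect_equal(r$ic[["S_B"]], 0)
  expect_equal(r$ic[["S_T"]], 1e6)
  expect_error(apply_overrides(p, ic, list(k9 = 1)), "unknown override.*k9")
  expect_error(apply_overrides(p, ic, list(1)), "named")
})

test_that("rhs reduces to naive influx on the empty state", {
  zero <- setNames(rep(0, 8), state_names())
  d <- evaluate_rhs(zero, base_p)
  expect_equal(d[["E_N"]], 90)
  expect_equal(unname(d[setdiff(state_names(), "E_N")]), rep(0, 7))
})

test_that("rhs on a pure blood bolus moves bacteria into the tumor", {
  st <- setNames(rep(0, 8), state_names())
  st[["S_B"]] <- 1e6
  d <- evaluate_rhs(st, base_p)
  expect_equal(d[["S_B"]], -5e5)
  expect_equal(d[["S_T"]], 5e5)
  expect_equal(d[["E_N"]], 90)
  expect_equal(unname(d[c("T_U", "T_I", "E_B", "E_T", "I_C")]), rep(0, 5))
})

test_that("rhs matches a hand-evaluated oracle on the baseline cold state", {
  # Independent arithmetic, written out term by term from the model
  # equations at S_B = 1e6, T_U = 1e6, E_N = 100, I_C = 10, rest 0.
  st <- c(S_B = 1e6, S_T = 0, T_U = 1e6, T_I = 0,
          E_B = 0, E_T = 0, E_N = 100, I_C = 10)
  expected <- c(
    S_B = -0.5 * 1e6,
    S_T = 0.5 * 1e6,
    T_U = 0.43 * 1e6 * (1 - 1.02e-9 * 1e6),
    T_I = 0,
    E_B = 0,
    E_T = 1.23 * 100 * (1e6 / (2.5e3 + 1e6)) * (10 / (120 + 10)),
    E_N = 90 - 1.23 * 100 * (1e6 / (2.5e3 + 1e6)),
    I_C = -0.5137 * 10
  )
  expect_equal(evaluate_rhs(st, base_p), expected, tolerance = 1e-12)
})

test_that("rhs validation names the offending component", {
  st <- setNames(rep(0, 8), state_names())
  st[["T_U"]] <- -1
  expect_error(evaluate_rhs(st, base_p), "negative state component.*T_U")
  st[["T_U"]] <- NaN
  expect_error(evaluate_rhs(st, base_p), "non-finite state component.*T_U")
})

test_that("rhs is exactly linear in the naive influx i", {
  set.seed(4)
  for (rep in 1:5) {
    st <- setNames(10^stats::runif(8, 0, 6), state_names())
    for (delta in c(1, 17.5, 400)) {
      p2 <- base_p
      p2[["i"]] <- base_p[["i"]] + delta
      d1 <- evaluate_rhs(st, base_p)
      d2 <- evaluate_rhs(st, p2)
      expect_equal(d2[["E_N"]] - d1[["E_N"]], delta)
      expect_equal(d2[setdiff(state_names(), "E_N")],
                   d1[setdiff(state_names(), "E_N")])
    }
  }
})

test_that("tumor equation reduces to the logistic form without killers", {
  for (tu in c(10, 1e5, 5e8)) {
    st <- setNames(rep(0, 8), state_names())
    st[["T_U"]] <- tu
    d <- evaluate_rhs(st, base_p)
    expect_equal(d[["T_U"]],
                 base_p[["a"]] * tu * (1 - base_p[["b"]] * tu))
  }
})

test_that("zero cytokines gate off both T cell activation terms", {
  st <- c(S_B = 0, S_T = 1e4, T_U = 1e6, T_I = 1e4,
          E_B = 50, E_T = 50, E_N = 100, I_C = 0)
  d <- evaluate_rhs(st, base_p)
  # with I_C = 0 the only E_B/E_T terms left are the losses
  expect_equal(d[["E_B"]],
               -base_p[["d2"]] * 50 * 1e4 - base_p[["d3"]] * 50)
  expect_equal(d[["E_T"]],
               -base_p[["d2"]] * 50 * (1e6 + 1e4) - base_p[["d3"]] * 50)
})

test_that("derivatives stay finite across random non-negative states", {
  set.seed(11)
  for (rep in 1:25) {
    st <- setNames(10^stats::runif(8, -3, 9), state_names())
    st[sample(8, sample(0:3, 1))] <- 0
    expect_true(all(is.finite(evaluate_rhs(st, base_p))))
  }
})
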