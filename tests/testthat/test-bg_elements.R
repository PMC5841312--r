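# Bond-graph compartment library: state layouts, fixed points, junction
# conservation, the Voigt wrapper, and passivity.

test_that("state-vector width is fixed by the type tag, viscoelastic or not", {
  widths <- c(PV = 2, VP = 2, PP = 3, VV = 3, PV_SPLIT = 2, VV_MERGE = 3,
              PP_BC_TERMINAL = 3)
  for (tag in segment_types()) {
    expect_length(seg_state_slots(tag), widths[[tag]])
    ve <- seg_state_slots(tag, viscoelastic = TRUE)
    expect_length(ve, widths[[tag]])   # mu_v replaces mu, width unchanged
    expect_true("uv" %in% ve)
  }
})

test_that("every segment type has zero derivatives at its analytic fixed point", {
  set.seed(11)
  for (i in 1:20) {
    p <- random_params()
    u_in <- runif(1, 500, 15000); u_out <- runif(1, 0, 400)
    vbar <- runif(1, 1e-6, 1e-4)

    # PV: v = v_out, u = u_in - v R
    d <- deriv_pv(c(u = u_in - vbar * p$R, v = vbar),
                  list(u_in = u_in, v_out = vbar), p)
    expect_equal(unname(d), c(0, 0))
    # quiescent state
    d0 <- deriv_pv(c(u = u_in, v = 0), list(u_in = u_in, v_out = 0), p)
    expect_equal(unname(d0), c(0, 0))

    # VP: v = v_in, u = u_out + v R
    d <- deriv_vp(c(u = u_out + vbar * p$R, v = vbar),
                  list(v_in = vbar, u_out = u_out), p)
    expect_equal(unname(d), c(0, 0))

    # PP: v = vd = (u_in - u_out)/R, u = (u_in + u_out)/2
    v <- (u_in - u_out) / p$R
    d <- deriv_pp(c(u = (u_in + u_out) / 2, v = v, vd = v),
                  list(u_in = u_in, u_out = u_out), p)
    expect_equal(unname(d), c(0, 0, 0))

    # VV: v = v_in = v_out, u - ud = v R
    d <- deriv_vv(c(u = u_out + vbar * p$R, v = vbar, ud = u_out),
                  list(v_in = vbar, v_out = vbar), p)
    expect_equal(unname(d), c(0, 0, 0))

    # split: v = sum of daughters, u = u_in - v R
    d <- deriv_pv_split(c(u = u_in - vbar * p$R, v = vbar),
                        list(u_in = u_in, v_daughters = c(vbar / 2, vbar / 2)), p)
    expect_equal(unname(d), c(0, 0))

    # merge: v = sum of feeder flows, u - ud = v R
    d <- deriv_vv_merge(c(u = u_out + vbar * p$R, v = vbar, ud = u_out),
                        list(vd_in = c(vbar / 3, 2 * vbar / 3), v_out = vbar), p)
    expect_equal(unname(d), c(0, 0, 0))

    # terminal: constant inflow vbar, pressure cascade of the RCR circuit
    term <- terminal_params(RTP = 1e7, RTD = 1e8, CT = 1e-9,
                            mu_out = u_out)
    ud <- vbar * term$RTD
    u <- ud + u_out + vbar * term$RTP
    d <- deriv_pp_bc_terminal(c(u = u, v = vbar, ud = ud),
                              list(u_in = u + vbar * p$R, u_out = u_out),
                              p, term)
    expect_equal(unname(as.numeric(d)), c(0, 0, 0))
    expect_equal(attr(d, "vd"), vbar)   # drop u -> mu_out is vbar (RTP+RTD)
  }
})

test_that("a one-daughter split reduces exactly to the plain mu-upsilon type", {
  set.seed(5)
  for (i in 1:10) {
    p <- random_params()
    st <- c(u = runif(1, 0, 1e4), v = runif(1, -1e-4, 1e-4))
    u_in <- runif(1, 0, 1e4); vq <- runif(1, -1e-4, 1e-4)
    expect_identical(
      deriv_pv_split(st, list(u_in = u_in, v_daughters = vq), p),
      deriv_pv(st, list(u_in = u_in, v_out = vq), p))
  }
})

test_that("junction laws hold algebraically at arbitrary states", {
  set.seed(23)
  for (i in 1:20) {
    p <- random_params()
    st <- c(u = runif(1, 0, 1e4), v = runif(1, -1e-4, 1e-4))
    vq <- runif(3, -1e-4, 1e-4)
    # 0-junction at a split: C du/dt equals the signed flow sum exactly
    d <- deriv_pv_split(st, list(u_in = 0, v_daughters = vq), p)
    expect_equal(p$C * d[["u"]], st[["v"]] - sum(vq))
    # 0-junction at a merge
    stm <- c(st, ud = runif(1, 0, 1e4))
    dm <- deriv_vv_merge(stm, list(vd_in = vq, v_out = vq[1]), p)
    expect_equal((p$C / 2) * dm[["u"]], sum(vq) - stm[["v"]])
    # merge is linear in its feeder flows: symmetric daughters with equal
    # flow match one daughter carrying the doubled flow
    d2 <- deriv_vv_merge(stm, list(vd_in = c(vq[1], vq[1]), v_out = 0), p)
    d1 <- deriv_vv_merge(stm, list(vd_in = 2 * vq[1], v_out = 0), p)
    expect_identical(d2, d1)
    # 1-junction: potentials around the loop sum to zero
    # (I dv/dt + u + v R - u_in = 0 for the PV segment)
    u_in <- runif(1, 0, 1e4)
    dpv <- deriv_pv(st, list(u_in = u_in, v_out = 0), p)
    expect_equal(p$I * dpv[["v"]] + st[["u"]] + st[["v"]] * p$R - u_in, 0,
                 tolerance = 1e-8)
  }
})

test_that("Voigt wrapper: Rv -> 0 reduces to the elastic element; the dashpot carries the step", {
  set.seed(17)
  for (tag in c("PV", "VP", "PP", "VV", "PV_SPLIT", "VV_MERGE")) {
    p <- random_params()
    p0 <- lumped_params(p$R, p$C, p$I, Rv = 1e-300)  # effectively elastic
    slots <- seg_state_slots(tag, viscoelastic = TRUE)
    st <- stats::setNames(runif(length(slots), 0, 1e-4), slots)
    st[grep("^u", slots)] <- runif(length(grep("^u", slots)), 0, 1e4)
    bc <- switch(tag,
      PV = list(u_in = 1000, v_out = 1e-5),
      VP = list(v_in = 1e-5, u_out = 100),
      PP = list(u_in = 1000, u_out = 100),
      VV = list(v_in = 1e-5, v_out = 2e-5),
      PV_SPLIT = list(u_in = 1000, v_daughters = c(1e-5, 1e-5)),
      VV_MERGE = list(vd_in = c(1e-5, 1e-5), v_out = 2e-5))
    res <- deriv_segment(tag, st, bc, p0, viscoelastic = TRUE)
    est <- st
    names(est) <- sub("^uv$", "u", names(est))
    names(est) <- sub("^udv$", "ud", names(est))
    ref <- deriv_segment(tag, est, bc, p0, viscoelastic = FALSE)
    expect_equal(unname(res$deriv), unname(ref$deriv), tolerance = 1e-9)
    # with Rv ~ 0 the total pressure equals the elastic pressure
    expect_equal(res$pressures$u, st[["uv"]], tolerance = 1e-9)
  }

  # finite Rv: a step of the net capacitor inflow produces an
  # instantaneous pressure jump of (delta flow) * dashpot resistance
  p <- random_params()
  dflow <- 3e-5
  st <- c(uv = 8000, v = 2e-5)
  r1 <- apply_viscoelastic(st, list(u_in = 1e4, v_out = 2e-5), p, tag = "PV")
  r2 <- apply_viscoelastic(st, list(u_in = 1e4, v_out = 2e-5 - dflow), p,
                           tag = "PV")
  expect_equal(r2$pressures$u - r1$pressures$u, dflow * p$Rv)

  # VV half-capacitors carry dashpots of 2 Rv (so Rv_half * C_half = f)
  stv <- c(uv = 8000, v = 2e-5, udv = 7000)
  b1 <- list(v_in = 2e-5, v_out = 2e-5)
  b2 <- list(v_in = 2e-5 + dflow, v_out = 2e-5 - dflow)
  r1 <- apply_viscoelastic(stv, b1, p, tag = "VV")
  r2 <- apply_viscoelastic(stv, b2, p, tag = "VV")
  expect_equal(r2$pressures$u - r1$pressures$u, dflow * 2 * p$Rv)
  expect_equal(r2$pressures$ud - r1$pressures$ud, dflow * 2 * p$Rv)
})

test_that("Voigt wrapper at steady state: zero net inflow means u equals uv", {
  p <- random_params()
  st <- c(uv = 9000, v = 4e-5)
  res <- apply_viscoelastic(st, list(u_in = 1e4, v_out = 4e-5), p, tag = "PV")
  expect_equal(res$pressures$u, 9000)
  # and the stored elastic state is then stationary
  expect_equal(res$deriv[["uv"]], 0)
})

test_that("passive elements dissipate: stored energy never increases with zero boundary input", {
  set.seed(29)
  for (i in 1:20) {
    p <- random_params()
    # PV with zero boundary pressure and blocked outlet
    st <- c(u = runif(1, -1e4, 1e4), v = runif(1, -1e-4, 1e-4))
    d <- deriv_pv(st, list(u_in = 0, v_out = 0), p)
    dE <- p$C * st[["u"]] * d[["u"]] + p$I * st[["v"]] * d[["v"]]
    expect_lte(dE, 1e-12)
    # PP with both boundary pressures zero
    st3 <- c(u = runif(1, -1e4, 1e4), v = runif(1, -1e-4, 1e-4),
             vd = runif(1, -1e-4, 1e-4))
    d3 <- deriv_pp(st3, list(u_in = 0, u_out = 0), p)
    dE3 <- p$C * st3[["u"]] * d3[["u"]] +
      (p$I / 2) * (st3[["v"]] * d3[["v"]] + st3[["vd"]] * d3[["vd"]])
    expect_lte(dE3, 1e-12)
  }
})
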