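test_that("shallow attention annihilates on zero context and passes through ones", {
  f <- rand_fmap(4, 4, 2)
  zero_deep <- array(0, dim = c(2, 2, 2))
  expect_equal(shallow_attention(f, zero_deep)$features, f * 0)
  ones_deep <- array(1, dim = c(4, 4, 2))
  expect_equal(shallow_attention(f, ones_deep)$features, f)
})

test_that("shallow attention on a constant deeper map scales the features", {
  f <- array(c(1, 3, 2, 4), dim = c(2, 2, 1))   # [[1,2],[3,4]]
  deep <- array(2, dim = c(1, 1, 1))
  got <- shallow_attention(f, deep)
  expect_equal(got$features, 2 * f)
  expect_equal(got$map, array(2, dim = c(2, 2, 1)))
})

test_that("three-input shallow attention applies both maps in sequence", {
  set.seed(7)
  f <- rand_fmap(4, 4, 3)
  f1 <- rand_fmap(2, 2, 3)
  f2 <- rand_fmap(1, 1, 3)
  got <- shallow_attention(f, f1, f2)
  expect_equal(got$features, oracle_shallow(f, f1, f2), tolerance = 1e-9)
  expect_true(all(got$map >= 0))
  expect_true(all(got$map2 >= 0))
})

test_that("reverse attention reverses the normalized map", {
  f <- rand_fmap(4, 4, 2)
  got0 <- reverse_attention(f, array(0, dim = c(2, 2, 2)))
  expect_equal(got0$features, 0.5 * f)          # sigmoid(0) = 1/2
  gotsat <- reverse_attention(f, array(100, dim = c(4, 4, 2)))
  expect_true(max(abs(gotsat$features)) < 1e-30 * max(abs(f)))
  gotln3 <- reverse_attention(f, array(log(3), dim = c(4, 4, 2)))
  expect_equal(gotln3$features, 0.25 * f, tolerance = 1e-12)
  # map + its complement reconstruct 1 and both stay in [0,1]
  m <- gotln3$map
  expect_true(all(m >= 0 & m <= 1))
  expect_equal(m + 0.75, array(1, dim = dim(m)), tolerance = 1e-12)
})

test_that("attention operators reject channel mismatches", {
  f <- rand_fmap(4, 4, 3)
  bad <- rand_fmap(2, 2, 2)
  expect_error(shallow_attention(f, bad), "channel")
  expect_error(reverse_attention(f, bad), "channel")
})

test_that("channel importance follows the squeeze arithmetic", {
  # GAP -> W -> ReLU -> Z, no biases
  f <- array(0, dim = c(2, 2, 2))
  f[, , 1] <- 2; f[, , 2] <- 4
  w <- matrix(c(1, 1), 1, 2)
  z <- matrix(c(1, 1), 2, 1)
  expect_equal(channel_importance(f, w, z), c(6, 6))
  # all-zero features give a zero vector (no bias terms)
  expect_equal(channel_importance(array(0, dim = c(3, 3, 2)), w, z), c(0, 0))
  # ReLU clips a negative squeeze output
  expect_equal(channel_importance(f, -w, z), c(0, 0))
})

test_that("operators match the scalar-loop oracles on random 4x4x3 inputs", {
  set.seed(202)
  for (rep in 1:8) {
    f <- rand_fmap(4, 4, 3)
    f1 <- rand_fmap(2, 2, 3)
    rel <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)
    expect_lt(rel(shallow_attention(f, f1)$features, oracle_shallow(f, f1)),
              1e-6)
    expect_lt(rel(reverse_attention(f, f1)$features, oracle_reverse(f, f1)),
              1e-6)
    gp <- gate_params(3)
    ci <- channel_importance(f, gp$w_sa, gp$z_sa)
    expect_lt(max(abs(ci - oracle_channel_importance(f, gp$w_sa, gp$z_sa))),
              1e-6)
    f_sa <- rand_fmap(4, 4, 3); f_ra <- rand_fmap(4, 4, 3)
    c_sa <- rnorm(3); c_ra <- rnorm(3)
    got <- softmax_gate(f_sa, f_ra, c_sa, c_ra)
    orc <- oracle_gate(f_sa, f_ra, c_sa, c_ra)
    expect_lt(rel(got$features, orc$features), 1e-6)
    expect_lt(max(abs(got$v_sa - orc$v_sa)), 1e-6)
  }
})

test_that("gate vectors are a valid two-way softmax", {
  set.seed(303)
  for (rep in 1:20) {
    c_sa <- rnorm(5, sd = 10); c_ra <- rnorm(5, sd = 10)
    f <- rand_fmap(3, 3, 5)
    g <- softmax_gate(f, f, c_sa, c_ra)
    expect_equal(g$v_sa + g$v_ra, rep(1, 5), tolerance = 1e-12)
    expect_true(all(g$v_sa > 0 & g$v_sa < 1))
    # logit-shift invariance
    shift <- rnorm(1, sd = 50)
    g2 <- softmax_gate(f, f, c_sa + shift, c_ra + shift)
    expect_equal(g$v_sa, g2$v_sa, tolerance = 1e-9)
  }
})

test_that("softmax fusion is convex and respects its limits", {
  set.seed(404)
  f_sa <- rand_fmap(4, 4, 3); f_ra <- rand_fmap(4, 4, 3)
  g <- softmax_gate(f_sa, f_ra, rnorm(3), rnorm(3))
  lo <- pmin(f_sa, f_ra); hi <- pmax(f_sa, f_ra)
  expect_true(all(g$features >= lo - 1e-12 & g$features <= hi + 1e-12))
  # equal logits halve the sum
  geq <- softmax_gate(f_sa, f_ra, c(1, 2, 3), c(1, 2, 3))
  expect_equal(geq$features, 0.5 * (f_sa + f_ra), tolerance = 1e-12)
  # a huge logit gap selects one branch outright
  gsel <- softmax_gate(f_sa, f_ra, c(1000, -1000, 0), c(0, 0, 0))
  expect_equal(gsel$features[, , 1], f_sa[, , 1])
  expect_equal(gsel$features[, , 2], f_ra[, , 2])
})

test_that("fusion modes relate algebraically", {
  set.seed(505)
  f_sa <- rand_fmap(4, 4, 3); f_ra <- rand_fmap(4, 4, 3)
  cs <- rnorm(3)
  expect_equal(fuse(f_sa, f_ra, "sum"),
               2 * fuse(f_sa, f_ra, "softmax", cs, cs), tolerance = 1e-12)
  expect_equal(fuse(f_sa, f_ra, "sigmoid", rep(0, 3), rep(0, 3)),
               0.5 * (f_sa + f_ra), tolerance = 1e-12)
  expect_equal(fuse(f_sa, array(0, dim = dim(f_ra)), "sum"), f_sa)
  expect_error(fuse(f_sa, f_ra, "product"))
})

test_that("operators accept a leading batch axis", {
  set.seed(606)
  fb <- array(rnorm(2 * 4 * 4 * 3), dim = c(2, 4, 4, 3))
  deep <- array(rnorm(2 * 2 * 2 * 3), dim = c(2, 2, 2, 3))
  got <- shallow_attention(fb, deep)
  expect_equal(dim(got$features), dim(fb))
  for (n in 1:2) {
    expect_equal(got$features[n, , , ],
                 oracle_shallow(array(fb[n, , , ], dim = c(4, 4, 3)),
                                array(deep[n, , , ], dim = c(2, 2, 3))),
                 tolerance = 1e-9)
  }
})
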