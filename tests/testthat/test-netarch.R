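# Closed-form layer/parameter/FLOP accounting of the network variants.

test_that("a single conv block has the closed-form parameter count", {
  # k = 3, c_in = 16, c_out = 32, batchnorm, no conv bias
  acc <- rootgrain:::convAccount(16, 32, 3, 1)
  expect_equal(unname(acc["params"]), 3 * 3 * 16 * 32 + 2 * 32)  # 4672
})

test_that("head strides distinguish base and elongated-target variants", {
  expect_equal(headStrides(buildSpec("n")), c(8, 16, 32))
  improved <- buildSpec("improved_n")
  expect_length(headStrides(improved), 5)
  expect_equal(max(headStrides(improved)), 4 * max(headStrides(buildSpec("n"))))
})

test_that("the improved backbone extends the baseline as a prefix", {
  n <- buildSpec("n")@layers
  imp <- buildSpec("improved_n")@layers
  # the whole n backbone (up to and including the pooling block) leads both
  for (i in 1:10) {
    expect_equal(imp[[i]]$kind, n[[i]]$kind)
    expect_equal(imp[[i]]$c1, n[[i]]$c1)
    expect_equal(imp[[i]]$c2, n[[i]]$c2)
  }
  # the two added stages are stride-2 convs with companion fusion blocks
  expect_equal(imp[[11]]$kind, "Conv"); expect_equal(imp[[11]]$s, 2)
  expect_equal(imp[[13]]$kind, "Conv"); expect_equal(imp[[13]]$s, 2)
})

test_that("parameter counts are additive and quadratic in width", {
  accN <- rootgrain:::accountSpec(buildSpec("n"))
  perLayer <- sum(vapply(buildSpec("n")@layers, function(l) {
    unname(rootgrain:::accountSpec(
      new("ArchitectureSpec", variant = "n", depthMult = 1, widthMult = 1,
          maxChannels = 1024, numClasses = 2, layers = list(l),
          headStrides = 8))["params"])
  }, numeric(1)))
  expect_equal(unname(accN["params"]), perLayer)

  # doubling channels of a pure conv multiplies weights by 4
  a1 <- rootgrain:::convAccount(64, 64, 3, 1)
  a2 <- rootgrain:::convAccount(128, 128, 3, 1)
  expect_equal((unname(a2["params"]) - 2 * 128) /
                 (unname(a1["params"]) - 2 * 64), 4)
})

test_that("variant ordering by parameters matches the published family", {
  p <- vapply(c("n", "s", "m", "l", "x"), function(v)
    countParams(buildSpec(v))$params_m, numeric(1))
  expect_true(all(diff(p) > 0))
  # the improved variant stays below the s variant
  pImp <- countParams(buildSpec("improved_n"))$params_m
  expect_gt(pImp, p[["n"]])
  expect_lt(pImp, p[["s"]])
})

test_that("FLOPs scale with the evaluation input size", {
  r320 <- countFlops(buildSpec("n"), inputSize = 320)
  r640 <- countFlops(buildSpec("n"), inputSize = 640)
  expect_equal(r640$flops / r320$flops, 4, tolerance = 1e-9)
  expect_equal(r640$input_size, 640)
})

test_that("training-target selection applies the aspect-ratio rule", {
  # 500 x 4 has aspect 125: removed when enforced, kept when not
  b <- data.frame(w = c(500, 0, 30, 4), h = c(4, 50, 30, 500))
  lim <- selectTrainingTargets(b, enforceAspectLimit = TRUE)
  free <- selectTrainingTargets(b, enforceAspectLimit = FALSE)
  expect_equal(lim$w, 30)
  expect_equal(free$w, c(500, 30, 4))    # zero-sized box removed in both modes

  # seeded random mix against a one-line reference filter
  for (seed in 1:10) {
    set.seed(seed)
    boxes <- data.frame(w = round(runif(10, -5, 600)),
                        h = round(runif(10, -5, 600)))
    for (enf in c(TRUE, FALSE)) {
      ref <- boxes[boxes$w > 0 & boxes$h > 0 &
                     (!enf | pmax(boxes$w / boxes$h, boxes$h / boxes$w) < 100), ]
      expect_equal(selectTrainingTargets(boxes, enf), ref,
                   ignore_attr = TRUE)
    }
  }
})

test_that("model configs round-trip through the YAML dialect", {
  for (v in c("n", "improved_n")) {
    spec <- buildSpec(v)
    txt <- exportModelConfig(spec)
    back <- importModelConfig(txt)
    expect_equal(back, spec)
    expect_equal(countParams(back)$params, countParams(spec)$params)
  }
  # the improved config lists 5 head inputs
  doc <- yaml::yaml.load(exportModelConfig(buildSpec("improved_n")))
  headEntry <- doc$head[[length(doc$head)]]
  expect_length(headEntry$from, 5)
})
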