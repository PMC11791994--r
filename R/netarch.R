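# Closed-form accounting of YoloV8seg-style layer graphs.
#
# Layouts are stored in the family's model-config convention: each entry is
# [from, repeats, module, args] with channel arguments in base (unscaled)
# units. A variant resolves the layout with its depth/width multipliers:
# channels become makeDivisible(min(c, maxChannels) * width, 8) and block
# repeats max(round(n * depth), 1). Counting conventions reproduce the
# family's reported summaries: "layers" enumerates unique modules of the
# flattened module tree (a Conv block is container + conv + batchnorm, with
# one shared activation counted once per model), parameters sum weight and
# affine-normalisation tensors, and FLOPs are twice the convolution
# multiply-accumulates plus normalisation element operations at an explicit
# input size.

makeDivisible <- function(x, divisor = 8) ceiling(x / divisor) * divisor

VARIANT_SCALES <- list(
  n = c(depth = 0.33, width = 0.25, maxch = 1024),
  s = c(depth = 0.33, width = 0.50, maxch = 1024),
  m = c(depth = 0.67, width = 0.75, maxch = 768),
  l = c(depth = 1.00, width = 1.00, maxch = 512),
  x = c(depth = 1.00, width = 1.25, maxch = 512)
)

# entry helper: from, repeats, module, args
L <- function(from, repeats, module, args = list()) {
  list(from = from, repeats = repeats, module = module, args = args)
}

yoloSegBackbone <- function() list(
  L(-1, 1, "Conv", list(64, 3, 2)),      # 0 P1/2
  L(-1, 1, "Conv", list(128, 3, 2)),     # 1 P2/4
  L(-1, 3, "C2f", list(128, TRUE)),      # 2
  L(-1, 1, "Conv", list(256, 3, 2)),     # 3 P3/8
  L(-1, 6, "C2f", list(256, TRUE)),      # 4
  L(-1, 1, "Conv", list(512, 3, 2)),     # 5 P4/16
  L(-1, 6, "C2f", list(512, TRUE)),      # 6
  L(-1, 1, "Conv", list(1024, 3, 2)),    # 7 P5/32
  L(-1, 3, "C2f", list(1024, TRUE)),     # 8
  L(-1, 1, "SPPF", list(1024, 5))        # 9
)

yoloSegLayout <- function() list(
  backbone = yoloSegBackbone(),
  head = list(
    L(-1, 1, "Upsample", list(2)),                 # 10
    L(list(-1, 6), 1, "Concat"),                   # 11
    L(-1, 3, "C2f", list(512)),                    # 12
    L(-1, 1, "Upsample", list(2)),                 # 13
    L(list(-1, 4), 1, "Concat"),                   # 14
    L(-1, 3, "C2f", list(256)),                    # 15 P3/8
    L(-1, 1, "Conv", list(256, 3, 2)),             # 16
    L(list(-1, 12), 1, "Concat"),                  # 17
    L(-1, 3, "C2f", list(512)),                    # 18 P4/16
    L(-1, 1, "Conv", list(512, 3, 2)),             # 19
    L(list(-1, 9), 1, "Concat"),                   # 20
    L(-1, 3, "C2f", list(1024)),                   # 21 P5/32
    L(list(15, 18, 21), 1, "Segment", list(32, 256))
  ),
  headStrides = c(8, 16, 32)
)

# Elongated-target variant: the baseline backbone is kept verbatim and two
# further stride-2 downsampling stages (P6/64, P7/128) broaden the receptive
# field; the neck runs top-down and bottom-up across all five scales and two
# large-target heads are appended at the new coarser strides. The fusion
# widths below (note the 768-wide P4 block) reconcile the layer graph with
# the published layer/parameter/FLOP accounting of this design.
improvedLayout <- function() list(
  backbone = c(yoloSegBackbone(), list(
    L(-1, 1, "Conv", list(1024, 3, 2)),    # 10 P6/64
    L(-1, 6, "C2f", list(1024, TRUE)),     # 11
    L(-1, 1, "Conv", list(1024, 3, 2)),    # 12 P7/128
    L(-1, 6, "C2f", list(1024, TRUE))      # 13
  )),
  head = list(
    L(-1, 1, "Upsample", list(2)),                 # 14
    L(list(-1, 11), 1, "Concat"),                  # 15
    L(-1, 3, "C2f", list(1024)),                   # 16 P6 fusion
    L(-1, 1, "Upsample", list(2)),                 # 17
    L(list(-1, 9), 1, "Concat"),                   # 18
    L(-1, 3, "C2f", list(1024)),                   # 19 P5 fusion
    L(-1, 1, "Upsample", list(2)),                 # 20
    L(list(-1, 6), 1, "Concat"),                   # 21
    L(-1, 3, "C2f", list(768)),                    # 22 P4 fusion
    L(-1, 1, "Upsample", list(2)),                 # 23
    L(list(-1, 4), 1, "Concat"),                   # 24
    L(-1, 3, "C2f", list(256)),                    # 25 P3/8
    L(-1, 1, "Conv", list(256, 3, 2)),             # 26
    L(list(-1, 22), 1, "Concat"),                  # 27
    L(-1, 3, "C2f", list(512)),                    # 28 P4/16
    L(-1, 1, "Conv", list(512, 3, 2)),             # 29
    L(list(-1, 19), 1, "Concat"),                  # 30
    L(-1, 3, "C2f", list(1024)),                   # 31 P5/32
    L(-1, 1, "Conv", list(1024, 3, 2)),            # 32
    L(list(-1, 16), 1, "Concat"),                  # 33
    L(-1, 3, "C2f", list(1024)),                   # 34 P6/64
    L(-1, 1, "Conv", list(1024, 3, 2)),            # 35
    L(list(-1, 13), 1, "Concat"),                  # 36
    L(-1, 3, "C2f", list(1024)),                   # 37 P7/128
    L(list(25, 28, 31, 34, 37), 1, "Segment", list(32, 256))
  ),
  headStrides = c(8, 16, 32, 64, 128)
)

#' Build the layer graph of a network variant
#'
#' Resolves a YoloV8seg-family layout into an [ArchitectureSpec] with scaled
#' channels, repeats and per-layer strides. Base variants (`"n"`, `"s"`,
#' `"m"`, `"l"`, `"x"`) follow the family's published layout with heads at
#' strides 8/16/32; `"improved_n"` extends the n backbone with two extra
#' stride-2 downsampling stages and appends two large-target detect/segment
#' heads at strides 64 and 128.
#'
#' @param variant one of `"n"`, `"s"`, `"m"`, `"l"`, `"x"`, `"improved_n"`.
#' @param numClasses number of object classes (default 2: primary and
#'   lateral roots).
#' @return an [ArchitectureSpec].
#' @examples
#' buildSpec("n")
#' headStrides(buildSpec("improved_n"))
#' @export
buildSpec <- function(variant = c("n", "s", "m", "l", "x", "improved_n"),
                      numClasses = 2) {
  variant <- match.arg(variant)
  base <- if (variant == "improved_n") "n" else variant
  sc <- VARIANT_SCALES[[base]]
  layout <- if (variant == "improved_n") improvedLayout() else yoloSegLayout()
  resolveLayout(layout, variant, sc[["depth"]], sc[["width"]], sc[["maxch"]],
                numClasses)
}

#' @rdname buildSpec
#' @param spec an [ArchitectureSpec].
#' @export
headStrides <- function(spec) spec@headStrides

resolveLayout <- function(layout, variant, depth, width, maxch, numClasses) {
  W <- function(c) makeDivisible(min(c, maxch) * width)
  D <- function(n) max(round(n * depth), 1)
  entries <- c(layout$backbone, layout$head)
  ch <- numeric(length(entries))     # output channels per layer index (1-based)
  strideOf <- numeric(length(entries))
  layers <- vector("list", length(entries))
  outCh <- function(i) if (i == 0) 3 else ch[i]
  outStride <- function(i) if (i == 0) 1 else strideOf[i]
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    from <- if (is.list(e$from)) vapply(e$from, function(f)
      if (f < 0) i - 1L + f + 1L else f + 1L, numeric(1)) else
      if (e$from < 0) i - 1L + e$from + 1L else e$from + 1L
    c1 <- outCh(from[1])
    st <- outStride(from[1])
    lay <- switch(e$module,
      Conv = {
        c2 <- W(e$args[[1]])
        st <- st * as.numeric(e$args[[3]])
        list(kind = "Conv", c1 = c1, c2 = c2, k = as.numeric(e$args[[2]]),
             s = as.numeric(e$args[[3]]))
      },
      C2f = {
        c2 <- W(e$args[[1]])
        list(kind = "C2f", c1 = c1, c2 = c2, n = D(e$repeats),
             shortcut = length(e$args) > 1 && isTRUE(e$args[[2]]))
      },
      SPPF = {
        c2 <- W(e$args[[1]])
        list(kind = "SPPF", c1 = c1, c2 = c2, k = as.numeric(e$args[[2]]))
      },
      Upsample = {
        c2 <- c1
        st <- st / as.numeric(e$args[[1]])
        list(kind = "Upsample", c1 = c1, c2 = c2,
             factor = as.numeric(e$args[[1]]))
      },
      Concat = {
        c2 <- sum(vapply(from, outCh, numeric(1)))
        list(kind = "Concat", c1 = c2, c2 = c2)
      },
      Segment = {
        chIn <- vapply(from, outCh, numeric(1))
        strides <- vapply(from, outStride, numeric(1))
        c2 <- 0
        list(kind = "Segment", ch = chIn, strides = strides,
             nc = as.numeric(numClasses), nm = as.numeric(e$args[[1]]),
             npr = W(e$args[[2]]), regMax = 16)
      },
      stop("unknown module: ", e$module))
    lay$from <- from
    lay$stride <- st
    lay$index <- i - 1L
    layers[[i]] <- lay
    ch[i] <- if (is.null(lay$c2)) 0 else lay$c2
    strideOf[i] <- st
  }
  new("ArchitectureSpec", variant = variant, depthMult = depth,
      widthMult = width, maxChannels = maxch, numClasses = numClasses,
      layers = layers, headStrides = layout$headStrides)
}

# per-layer accounting: returns c(params, modules, macs_at_hw) where hw is the
# H*W of the layer's OUTPUT feature map (flops use 2*macs + norm element ops)
convAccount <- function(c1, c2, k, hw) {
  c(params = k * k * c1 * c2 + 2 * c2,
    modules = 3,
    flops = 2 * k * k * c1 * c2 * hw + 4 * c2 * hw)
}

conv2dAccount <- function(c1, c2, k, hw, bias = TRUE) {
  c(params = k * k * c1 * c2 + if (bias) c2 else 0,
    modules = 1,
    flops = 2 * k * k * c1 * c2 * hw)
}

c2fAccount <- function(c1, c2, n, hw) {
  cm <- floor(0.5 * c2)
  acc <- convAccount(c1, 2 * cm, 1, hw) + convAccount((2 + n) * cm, c2, 1, hw)
  for (i in seq_len(n))
    acc <- acc + convAccount(cm, cm, 3, hw) + convAccount(cm, cm, 3, hw) +
      c(0, 1, 0)                                  # Bottleneck container
  acc + c(0, 2, 0)                                # C2f container + ModuleList
}

sppfAccount <- function(c1, c2, hw) {
  cm <- floor(c1 / 2)
  convAccount(c1, cm, 1, hw) + convAccount(4 * cm, c2, 1, hw) +
    c(0, 2, 0)                                    # container + MaxPool2d
}

segmentAccount <- function(lay, inputSize) {
  hws <- (inputSize / lay$strides)^2
  ch <- lay$ch
  c2 <- max(16, floor(ch[1] / 4), lay$regMax * 4)
  c3 <- max(ch[1], min(lay$nc, 100))
  c4 <- max(floor(ch[1] / 4), lay$nm)
  acc <- c(params = 0, modules = 3)               # Segment + cv2/cv3 ModuleLists
  acc <- c(acc, flops = 0)
  for (i in seq_along(ch)) {
    acc <- acc +
      convAccount(ch[i], c2, 3, hws[i]) + convAccount(c2, c2, 3, hws[i]) +
      conv2dAccount(c2, 4 * lay$regMax, 1, hws[i]) +
      convAccount(ch[i], c3, 3, hws[i]) + convAccount(c3, c3, 3, hws[i]) +
      conv2dAccount(c3, lay$nc, 1, hws[i]) +
      c(0, 2, 0)                                  # two Sequential containers
  }
  acc <- acc + c(lay$regMax, 2, 0)                # DFL container + fixed conv
  # proto branch on the finest level, upsampling to twice its resolution
  hw0 <- hws[1]
  acc <- acc + convAccount(ch[1], lay$npr, 3, hw0) +
    conv2dAccount(lay$npr, lay$npr, 2, hw0 * 4) + # ConvTranspose2d
    convAccount(lay$npr, lay$npr, 3, hw0 * 4) +
    convAccount(lay$npr, lay$nm, 1, hw0 * 4) +
    c(0, 1, 0)                                    # Proto container
  # mask-coefficient branch cv4
  acc <- acc + c(0, 1, 0)                         # cv4 ModuleList
  for (i in seq_along(ch)) {
    acc <- acc +
      convAccount(ch[i], c4, 3, hws[i]) + convAccount(c4, c4, 3, hws[i]) +
      conv2dAccount(c4, lay$nm, 1, hws[i]) +
      c(0, 1, 0)                                  # Sequential container
  }
  acc
}

accountSpec <- function(spec, inputSize = 640) {
  total <- c(params = 0, modules = 0, flops = 0)
  for (lay in spec@layers) {
    hw <- (inputSize / lay$stride)^2
    acc <- switch(lay$kind,
      Conv = convAccount(lay$c1, lay$c2, lay$k, hw),
      C2f = c2fAccount(lay$c1, lay$c2, lay$n, hw),
      SPPF = sppfAccount(lay$c1, lay$c2, hw),
      Upsample = c(params = 0, modules = 1, flops = 0),
      Concat = c(params = 0, modules = 1, flops = 0),
      Segment = segmentAccount(lay, inputSize))
    total <- total + acc
  }
  # model container, layer Sequential, and the single shared activation module
  total + c(0, 3, 0)
}

#' Count parameters, layers and FLOPs of a network variant
#'
#' Closed-form sums over the layer graph. `countParams()` reports trainable
#' parameters (weights plus affine normalisation terms), `countLayers()` the
#' module-enumeration count of the flattened graph (the convention under
#' which the family's published summaries are reported), and `countFlops()`
#' twice the convolution multiply-accumulates plus normalisation element
#' operations at an explicit input size (default 640 x 640, the family's
#' standard reporting size, recorded in the result).
#'
#' @param spec an [ArchitectureSpec] from [buildSpec()].
#' @param inputSize square input edge in pixels for FLOP evaluation.
#' @return `countParams()` and `countFlops()` return a list of class
#'   `CountReport` with fields `layer_count`, `params`, `params_m`, `flops`,
#'   `flops_g` and `input_size`; `countLayers()` returns the module count.
#' @examples
#' rep <- countParams(buildSpec("n"))
#' c(rep$layer_count, round(rep$params_m, 2), round(rep$flops_g, 1))
#' @export
countParams <- function(spec, inputSize = 640) {
  acc <- accountSpec(spec, inputSize)
  structure(list(variant = spec@variant,
                 layer_count = unname(acc["modules"]),
                 params = unname(acc["params"]),
                 params_m = unname(acc["params"]) / 1e6,
                 flops = unname(acc["flops"]),
                 flops_g = unname(acc["flops"]) / 1e9,
                 input_size = inputSize),
            class = "CountReport")
}

#' @rdname countParams
#' @export
countLayers <- function(spec) {
  unname(accountSpec(spec)["modules"])
}

#' @rdname countParams
#' @export
countFlops <- function(spec, inputSize = 640) {
  countParams(spec, inputSize)
}

#' @export
print.CountReport <- function(x, ...) {
  cat(sprintf("CountReport [%s @ %dx%d]: %d layers, %.2f M params, %.1f GFLOPs\n",
              x$variant, x$input_size, x$input_size, x$layer_count,
              x$params_m, x$flops_g))
  invisible(x)
}

#' Filter training target boxes
#'
#' The family's stock training scheme admits only labels whose boxes have
#' positive width and height and an aspect ratio below a limit (default 100),
#' which silently discards extremely elongated roots. The revised scheme drops
#' the aspect-ratio restriction so such roots contribute to training;
#' degenerate (zero-sized) boxes are always removed.
#'
#' @param boxes data.frame (or matrix) with columns `w`, `h` in pixels.
#' @param enforceAspectLimit apply the aspect-ratio restriction?
#' @param limit aspect-ratio limit (boxes with `max(w/h, h/w) >= limit` are
#'   removed when enforced).
#' @return the surviving rows of `boxes`.
#' @examples
#' b <- data.frame(w = c(500, 0, 30), h = c(4, 50, 30))
#' nrow(selectTrainingTargets(b, enforceAspectLimit = TRUE))   # 1
#' nrow(selectTrainingTargets(b, enforceAspectLimit = FALSE))  # 2
#' @export
selectTrainingTargets <- function(boxes, enforceAspectLimit = FALSE,
                                  limit = 100) {
  boxes <- as.data.frame(boxes)
  keep <- boxes$w > 0 & boxes$h > 0
  if (enforceAspectLimit) {
    ratio <- pmax(boxes$w / boxes$h, boxes$h / boxes$w)
    keep <- keep & ratio < limit
  }
  boxes[which(keep), , drop = FALSE]
}

#' Export / import a model configuration
#'
#' Writes the layer layout in the family's YAML model-config dialect (base
#' channel units plus the variant's scale factors); re-importing reproduces an
#' identical [ArchitectureSpec].
#'
#' @param spec an [ArchitectureSpec] built by [buildSpec()].
#' @param path optional file path; with `NULL` the YAML string is returned.
#' @export
exportModelConfig <- function(spec, path = NULL) {
  layout <- if (spec@variant == "improved_n") improvedLayout() else yoloSegLayout()
  ser <- function(e) {
    from <- if (is.list(e$from)) unlist(e$from) else e$from
    list(from = from, repeats = e$repeats, module = e$module,
         args = if (length(e$args)) e$args else list())
  }
  doc <- list(
    variant = spec@variant,
    nc = spec@numClasses,
    depth_multiple = spec@depthMult,
    width_multiple = spec@widthMult,
    max_channels = spec@maxChannels,
    head_strides = spec@headStrides,
    backbone = lapply(layout$backbone, ser),
    head = lapply(layout$head, ser)
  )
  txt <- yaml::as.yaml(doc)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname exportModelConfig
#' @param x YAML string or file path produced by [exportModelConfig()].
#' @export
importModelConfig <- function(x) {
  doc <- if (file.exists(x[1]) && !grepl("\n", x[1])) yaml::read_yaml(x) else
    yaml::yaml.load(x)
  des <- function(e) {
    from <- if (length(e$from) > 1) as.list(e$from) else e$from
    L(from, e$repeats, e$module, if (length(e$args)) e$args else list())
  }
  layout <- list(backbone = lapply(doc$backbone, des),
                 head = lapply(doc$head, des),
                 headStrides = as.numeric(doc$head_strides))
  resolveLayout(layout, doc$variant, as.numeric(doc$depth_multiple),
                as.numeric(doc$width_multiple), as.numeric(doc$max_channels),
                as.numeric(doc$nc))
}
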