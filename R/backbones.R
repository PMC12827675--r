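## Backbone registry for the dual-branch classifier. Each builder returns the
## feature-extraction trunk of a published CNN (classification head removed);
## the registry pins each architecture's shallow/deep category and the channel
## width of its final feature map. TinyCNN is a compact trunk intended for
## CPU-scale training and tests; it may occupy either branch slot.

build_tinycnn <- function() {
  net <- nn_sequential(
    layer_conv(3, 16, 7, stride = 4, pad = 3), layer_bn(16), layer_relu(),
    layer_maxpool(2),
    layer_conv(16, 32, 3, stride = 1, pad = 1), layer_bn(32), layer_relu(),
    layer_maxpool(2),
    layer_conv(32, 32, 3, stride = 1, pad = 1), layer_bn(32), layer_relu())
  list(net = net, feature_dim = 32L)
}

build_alexnet <- function() {
  net <- nn_sequential(
    layer_conv(3, 64, 11, stride = 4, pad = 2), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(64, 192, 5, stride = 1, pad = 2), layer_relu(),
    layer_maxpool(3, 2),
    layer_conv(192, 384, 3, stride = 1, pad = 1), layer_relu(),
    layer_conv(384, 256, 3, stride = 1, pad = 1), layer_relu(),
    layer_conv(256, 256, 3, stride = 1, pad = 1), layer_relu(),
    layer_maxpool(3, 2))
  list(net = net, feature_dim = 256L)
}

conv_bn <- function(in_ch, out_ch, k, stride = 1, pad = 0, groups = 1) {
  list(layer_conv(in_ch, out_ch, k, stride, pad, groups), layer_bn(out_ch))
}

basic_block <- function(in_ch, out_ch, stride) {
  body <- nn_sequential(c(
    conv_bn(in_ch, out_ch, 3, stride, 1), list(layer_relu()),
    conv_bn(out_ch, out_ch, 3, 1, 1)))
  sc <- if (stride != 1 || in_ch != out_ch)
    nn_sequential(conv_bn(in_ch, out_ch, 1, stride))
  nn_residual(body, sc)
}

bottleneck_block <- function(in_ch, planes, stride, groups = 1,
                             base_width = 64) {
  width <- as.integer(planes * (base_width / 64)) * groups
  out_ch <- planes * 4L
  body <- nn_sequential(c(
    conv_bn(in_ch, width, 1), list(layer_relu()),
    conv_bn(width, width, 3, stride, 1, groups), list(layer_relu()),
    conv_bn(width, out_ch, 1)))
  sc <- if (stride != 1 || in_ch != out_ch)
    nn_sequential(conv_bn(in_ch, out_ch, 1, stride))
  nn_residual(body, sc)
}

build_resnet <- function(block, counts, bottleneck = FALSE,
                         groups = 1, base_width = 64) {
  layers <- c(conv_bn(3, 64, 7, 2, 3), list(layer_relu(), layer_maxpool(3, 2, 1)))
  in_ch <- 64L
  planes <- c(64L, 128L, 256L, 512L)
  for (s in seq_along(counts)) {
    for (b in seq_len(counts[s])) {
      stride <- if (b == 1L && s > 1L) 2L else 1L
      blk <- if (bottleneck)
        bottleneck_block(in_ch, planes[s], stride, groups, base_width)
      else basic_block(in_ch, planes[s], stride)
      layers <- c(layers, list(blk))
      in_ch <- if (bottleneck) planes[s] * 4L else planes[s]
    }
  }
  list(net = nn_sequential(layers), feature_dim = in_ch)
}

dense_unit <- function(in_ch, growth) {
  nn_sequential(c(
    list(layer_bn(in_ch), layer_relu()),
    list(layer_conv(in_ch, 4L * growth, 1)),
    list(layer_bn(4L * growth), layer_relu()),
    list(layer_conv(4L * growth, growth, 3, 1, 1))))
}

build_densenet <- function(counts, growth = 32L, init_ch = 64L) {
  layers <- c(conv_bn(3, init_ch, 7, 2, 3),
              list(layer_relu(), layer_maxpool(3, 2, 1)))
  ch <- init_ch
  for (s in seq_along(counts)) {
    units <- vector("list", counts[s])
    for (u in seq_len(counts[s]))
      units[[u]] <- dense_unit(ch + (u - 1L) * growth, growth)
    layers <- c(layers, list(nn_dense_block(units)))
    ch <- ch + counts[s] * growth
    if (s < length(counts)) {
      layers <- c(layers, list(layer_bn(ch), layer_relu(),
                               layer_conv(ch, ch %/% 2L, 1),
                               layer_avgpool(2)))
      ch <- ch %/% 2L
    }
  }
  layers <- c(layers, list(layer_bn(ch), layer_relu()))
  list(net = nn_sequential(layers), feature_dim = ch)
}

inverted_residual <- function(in_ch, out_ch, stride, expand) {
  mid <- in_ch * expand
  body_layers <- list()
  if (expand != 1L)
    body_layers <- c(conv_bn(in_ch, mid, 1), list(layer_relu6()))
  body_layers <- c(body_layers,
                   conv_bn(mid, mid, 3, stride, 1, groups = mid),
                   list(layer_relu6()),
                   conv_bn(mid, out_ch, 1))
  body <- nn_sequential(body_layers)
  if (stride == 1L && in_ch == out_ch)
    nn_residual(body, NULL, post_relu = FALSE)
  else body
}

build_mobilenetv2 <- function() {
  cfg <- rbind( # expand, out, repeats, stride
    c(1, 16, 1, 1), c(6, 24, 2, 2), c(6, 32, 3, 2), c(6, 64, 4, 2),
    c(6, 96, 3, 1), c(6, 160, 3, 2), c(6, 320, 1, 1))
  layers <- c(conv_bn(3, 32, 3, 2, 1), list(layer_relu6()))
  in_ch <- 32L
  for (r in seq_len(nrow(cfg))) {
    for (i in seq_len(cfg[r, 3])) {
      stride <- if (i == 1L) cfg[r, 4] else 1L
      layers <- c(layers,
                  list(inverted_residual(in_ch, cfg[r, 2], stride, cfg[r, 1])))
      in_ch <- cfg[r, 2]
    }
  }
  layers <- c(layers, conv_bn(in_ch, 1280, 1), list(layer_relu6()))
  list(net = nn_sequential(layers), feature_dim = 1280L)
}

.backbone_table <- list(
  TinyCNN     = list(category = "any",     build = build_tinycnn,
                     feature_dim = 32L),
  MobileNetV2 = list(category = "shallow", build = build_mobilenetv2,
                     feature_dim = 1280L),
  AlexNet     = list(category = "shallow", build = build_alexnet,
                     feature_dim = 256L),
  ResNet18    = list(category = "shallow",
                     build = function() build_resnet(NULL, c(2, 2, 2, 2)),
                     feature_dim = 512L),
  ResNet50    = list(category = "deep",
                     build = function()
                       build_resnet(NULL, c(3, 4, 6, 3), bottleneck = TRUE),
                     feature_dim = 2048L),
  ResNeXt50   = list(category = "deep",
                     build = function()
                       build_resnet(NULL, c(3, 4, 6, 3), bottleneck = TRUE,
                                    groups = 32, base_width = 4),
                     feature_dim = 2048L),
  DenseNet121 = list(category = "deep",
                     build = function() build_densenet(c(6, 12, 24, 16)),
                     feature_dim = 1024L),
  DenseNet201 = list(category = "deep",
                     build = function() build_densenet(c(6, 12, 48, 32)),
                     feature_dim = 1920L)
)

#' Available backbone architectures
#'
#' Lists the feature-extraction backbones that can fill the shallow or deep
#' branch of the dual-branch classifier, their branch category, and the
#' channel width of the final convolutional feature map. The taxonomy is
#' fixed by the registry (`shallow`, `deep`, or `any`); it is not recomputed
#' from layer counts.
#'
#' @return a data.frame with columns `name`, `category`, `feature_dim`.
#' @export
#' @examples
#' backbone_registry()
backbone_registry <- function() {
  data.frame(name = names(.backbone_table),
             category = vapply(.backbone_table, `[[`, "", "category"),
             feature_dim = vapply(.backbone_table, function(e)
               as.integer(e$feature_dim), integer(1)),
             row.names = NULL)
}

lookup_backbone <- function(name) {
  hit <- match(tolower(name), tolower(names(.backbone_table)))
  if (is.na(hit))
    stop("unknown backbone '", name, "'; available: ",
         paste(names(.backbone_table), collapse = ", "))
  c(list(name = names(.backbone_table)[hit]), .backbone_table[[hit]])
}
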