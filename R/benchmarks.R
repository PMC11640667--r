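# Published benchmark accuracies from the 54-goat multi-view study that
# motivates this package, shipped as plain CSVs: one table of the 20
# single-view models (4 backbones x 5 views) and one of the 40 dual-view
# fusion models (4 backbones x 10 view pairs). All values are percentages
# on a 5,400-image test set (20 images x 54 animals x 5 views). They serve
# as worked-example inputs for aggregate_accuracy_table() -- per-backbone
# and per-view averages, best/worst view pairs, fusion gains -- and as
# realistic per-view accuracy settings for the confidence simulator.

#' Published single-view benchmark results
#'
#' Top-1/Top-5 accuracy and macro precision/recall/F1 (percent) of the 20
#' single-view identification models: four convolutional backbones
#' (MobileNetV3, MobileViT, ResNet18, VGG16), each trained on one of the
#' five appearance views of a 54-animal goat herd.
#'
#' @return `data.frame` with columns `model`, `backbone`, `view`, `top1`,
#'   `top5`, `mean_precision`, `mean_recall`, `mean_f1`.
#' @export
single_view_benchmark <- function() {
  read.csv(system.file("extdata", "single_view_results.csv",
                       package = "caprid"),
           stringsAsFactors = FALSE)
}

#' Published dual-view fusion benchmark results
#'
#' The same metrics for the 40 dual-view fusion models (each backbone
#' fusing every pair of the five views by accuracy-weighted averaging).
#'
#' @return `data.frame` with columns `model`, `backbone`, `combination`,
#'   `top1`, `top5`, `mean_precision`, `mean_recall`, `mean_f1`.
#' @export
dual_view_benchmark <- function() {
  read.csv(system.file("extdata", "dual_view_results.csv",
                       package = "caprid"),
           stringsAsFactors = FALSE)
}
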