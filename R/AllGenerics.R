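#' @import methods
#' @importFrom stats rnorm runif plogis qnorm dnorm sd cor cor.test wilcox.test
#'   p.adjust lm coef vcov pt glm binomial predict quantile median setNames
#'   as.dist hclust cutree as.hclust phyper complete.cases t.test var dist
#'   qlogis
#' @importFrom utils read.delim write.table head tail
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assayNames
#'   colData rowData
#' @importFrom S4Vectors DataFrame metadata
NULL

#' @rdname MetaboSet-class
#' @export
setGeneric("intensities", function(x) standardGeneric("intensities"))

#' @rdname MetaboSet-class
#' @export
setGeneric("missingMask", function(x) standardGeneric("missingMask"))

#' @rdname MetaboSet-class
#' @export
setGeneric("procStage", function(x) standardGeneric("procStage"))

#' @rdname MetaboSet-class
#' @export
setGeneric("vip", function(object) standardGeneric("vip"))
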