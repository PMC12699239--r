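#' @rdname MiRExperiment
#' @param x a \linkS4class{MiRExperiment}
#' @export
setGeneric("relExpr", function(x) standardGeneric("relExpr"))

#' @rdname MiRExperiment
#' @export
setGeneric("referenceAssays", function(x) standardGeneric("referenceAssays"))

#' @rdname MiRExperiment
#' @export
setGeneric("calibratorGroup", function(x) standardGeneric("calibratorGroup"))

#' @rdname MiRExperiment
#' @export
setGeneric("sampleGroups", function(x) standardGeneric("sampleGroups"))

#' @rdname RocCurve-accessors
#' @param x a \linkS4class{RocCurve} or \linkS4class{PanelPerformance}
#' @export
setGeneric("auc", function(x) standardGeneric("auc"))

#' @rdname LogisticFit-accessors
#' @param x a \linkS4class{LogisticFit}
#' @export
setGeneric("oddsRatio", function(x) standardGeneric("oddsRatio"))

#' @rdname PanelPerformance-accessors
#' @param x a \linkS4class{PanelPerformance}
#' @export
setGeneric("perK", function(x) standardGeneric("perK"))

#' @rdname PanelPerformance-accessors
#' @export
setGeneric("bestK", function(x) standardGeneric("bestK"))

#' @rdname PanelPerformance-accessors
#' @export
setGeneric("voteCounts", function(x) standardGeneric("voteCounts"))
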