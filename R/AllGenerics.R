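#' @include AllClasses.R
NULL

#' @rdname CellCohort-accessors
#' @export
setGeneric("donorData", function(x) standardGeneric("donorData"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("donorIds", function(x) standardGeneric("donorIds"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("donorAges", function(x) standardGeneric("donorAges"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("cellDonors", function(x) standardGeneric("cellDonors"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("cellTypeLabels", function(x) standardGeneric("cellTypeLabels"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname CellCohort-accessors
#' @export
setGeneric("isNormalized", function(x) standardGeneric("isNormalized"))

#' @rdname DonorFeatureMatrix-accessors
#' @export
setGeneric("featureMatrix", function(x) standardGeneric("featureMatrix"))
#' @rdname DonorFeatureMatrix-accessors
#' @export
setGeneric("donorAgesOf", function(x) standardGeneric("donorAgesOf"))
#' @rdname DonorFeatureMatrix-accessors
#' @export
setGeneric("columnMeta", function(x) standardGeneric("columnMeta"))

#' @rdname AgeEvaluation-accessors
#' @export
setGeneric("meanR2", function(x) standardGeneric("meanR2"))
#' @rdname AgeEvaluation-accessors
#' @export
setGeneric("sdR2", function(x) standardGeneric("sdR2"))
#' @rdname AgeEvaluation-accessors
#' @export
setGeneric("r2PerRun", function(x) standardGeneric("r2PerRun"))
#' @rdname AgeEvaluation-accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))

#' @rdname ImportanceReport-accessors
#' @export
setGeneric("shapValues", function(x) standardGeneric("shapValues"))
#' @rdname ImportanceReport-accessors
#' @export
setGeneric("geneScores", function(x) standardGeneric("geneScores"))
#' @rdname ImportanceReport-accessors
#' @export
setGeneric("genePValues", function(x) standardGeneric("genePValues"))

#' @rdname GeneSet-accessors
#' @export
setGeneric("setName", function(x) standardGeneric("setName"))
#' @rdname GeneSet-accessors
#' @export
setGeneric("members", function(x) standardGeneric("members"))
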