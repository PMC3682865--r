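#' @keywords internal
"_PACKAGE"

#' @importFrom methods new is validObject setValidity initialize slot
#' @importFrom stats median rnorm sd setNames predict
#' @importFrom utils adist write.csv
#' @importFrom randomForest randomForest
NULL

.onLoad <- function(libname, pkgname) {
  .registerDefaultFeatures()
  registerScorer("default-nb", .defaultNBScorer)
  registerModelBackend("rf", .rfBackend())
  invisible()
}
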