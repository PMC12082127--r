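#' Construct a RoutingPolicy
#'
#' Defaults encode the operating policy of the pipeline: the small-variant
#' genotyper is trusted for changes below 50 bp; the bridging SV caller
#' covers the 50--99 bp gap between the small-variant caller's maximum and
#' the primary SV caller's 100 bp floor; read-depth segments are split
#' between an autosomal caller and a sex-chromosome caller, the latter
#' filtered at Q0 < 0.5, p_N < 0.5 and p-value < 0.001 (all strict).
#'
#' @param smallMaxSize Small-variant caller maximum size change in bp
#'   (exclusive).
#' @param svMinSize Primary SV caller minimum length in bp (inclusive).
#' @param bridgeMin,bridgeMax Bridging caller window \code{[min, max)};
#'   must abut the neighbouring ranges (no gap, no overlap).
#' @param q0Max,pNMax,pMax Depth-segment thresholds (strict inequalities).
#' @param callerRoles Named character mapping caller ids to roles.
#' @param callerOrder Tie-breaking priority of callers when merged calls
#'   have equal quality; defaults to the order of \code{callerRoles}.
#' @return A \code{\linkS4class{RoutingPolicy}}.
#' @examples
#' routingPolicy()
#' @export
routingPolicy <- function(smallMaxSize = 50, svMinSize = 100,
                          bridgeMin = smallMaxSize, bridgeMax = svMinSize,
                          q0Max = 0.5, pNMax = 0.5, pMax = 0.001,
                          callerRoles = c(clair3 = "small",
                                          nanovar = "bridge",
                                          debreak = "primary_sv",
                                          qdnaseq = "depth_autosome",
                                          cnvpytor = "depth_sexchrom",
                                          sniffles = "repeat",
                                          paraphase = "haplotype"),
                          callerOrder = names(callerRoles)) {
  methods::new("RoutingPolicy", smallMaxSize = smallMaxSize,
               bridgeMin = bridgeMin, bridgeMax = bridgeMax,
               svMinSize = svMinSize, q0Max = q0Max, pNMax = pNMax,
               pMax = pMax, callerRoles = callerRoles,
               callerOrder = callerOrder)
}

setMethod("show", "RoutingPolicy", function(object) {
  cat("RoutingPolicy\n",
      "  small-variant caller: |size| < ", object@smallMaxSize, " bp\n",
      "  bridging SV caller:   [", object@bridgeMin, ", ",
      object@bridgeMax, ") bp\n",
      "  primary SV caller:    >= ", object@svMinSize, " bp\n",
      "  depth thresholds:     Q0 < ", object@q0Max, ", p_N < ",
      object@pNMax, ", p < ", object@pMax, "\n", sep = "")
  roles <- paste0(names(object@callerRoles), "=", object@callerRoles)
  cat("  roles: ", paste(roles, collapse = ", "), "\n", sep = "")
  invisible(NULL)
})
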