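# Dynamic network construction: per-time activity filtering and the
# induced time-sequenced subnetworks (TSNs).

#' Proteins active at one time point
#'
#' A gene is active at time `t` when its measured expression value is at
#' least `threshold`. Missing measurements are never active, whatever the
#' threshold: no imputation is attempted, matching the conservative intent
#' of the expression filter.
#'
#' @param expr an [ExpressionSeries-class].
#' @param t time index in `1..k`.
#' @param threshold activity threshold in expression units (the usual
#'   choice for scaled time-course data is 0.7).
#' @return character vector of active gene IDs.
#' @export
#' @examples
#' e <- expressionSeries(matrix(c(0.9, 0.5), 2, 1,
#'                       dimnames = list(c("A", "B"), "t1")))
#' activeProteins(e, 1, 0.7)  # "A"
activeProteins <- function(expr, t, threshold) {
    stopifnot(methods::is(expr, "ExpressionSeries"))
    v <- exprValues(expr)
    t <- as.integer(t)
    if (length(t) != 1 || is.na(t) || t < 1 || t > ncol(v))
        stop("time index out of range: must lie in 1..", ncol(v), call. = FALSE)
    if (!is.finite(threshold) && !identical(threshold, -Inf))
        stop("threshold must be finite (or -Inf for no filtering)", call. = FALSE)
    x <- v[, t]
    rownames(v)[!is.na(x) & x >= threshold]
}

#' Build the series of time-sequenced subnetworks
#'
#' Splits a static interaction network into one subnetwork per expression
#' time point: TSN i is the subgraph induced on the proteins active at time
#' i (see [activeProteins()]). Active proteins with no active interaction
#' partner are kept as degree-0 vertices, preserving induced-subgraph
#' semantics. Proteins in the network but absent from the expression matrix
#' are inactive at every time by default.
#'
#' @param network the static [InteractionNetwork-class].
#' @param expr an [ExpressionSeries-class] with k time points.
#' @param threshold activity threshold (default 0.7).
#' @param unmeasured policy for network proteins without expression rows:
#'   `"inactive"` (default, excluded from every TSN) or `"active"` (kept in
#'   every TSN).
#' @param quiet suppress the per-TSN size summary message.
#' @return a [TSNSeries-class] of k subnetworks.
#' @export
buildTSNSeries <- function(network, expr, threshold = 0.7,
                           unmeasured = c("inactive", "active"),
                           quiet = FALSE) {
    stopifnot(methods::is(network, "InteractionNetwork"),
              methods::is(expr, "ExpressionSeries"))
    unmeasured <- match.arg(unmeasured)
    prot <- proteins(network)
    measured <- intersect(prot, genes(expr))
    if (length(measured) == 0)
        stop("no overlap between network proteins and expression genes; ",
             "nothing to build", call. = FALSE)
    always <- if (unmeasured == "active") setdiff(prot, genes(expr)) else character()
    k <- ncol(exprValues(expr))
    g <- asIgraph(network)
    tsns <- vector("list", k)
    active <- vector("list", k)
    for (i in seq_len(k)) {
        act <- sort(unique(c(intersect(activeProteins(expr, i, threshold), prot),
                             always)))
        sub <- igraph::induced_subgraph(g, act)
        tsns[[i]] <- methods::new("InteractionNetwork", graph = sub)
        active[[i]] <- act
    }
    if (!quiet)
        message(sprintf("built %d TSNs (threshold %g): %d-%d active proteins, %d-%d interactions per TSN",
                        k, threshold,
                        min(lengths(active)), max(lengths(active)),
                        min(vapply(tsns, numInteractions, integer(1))),
                        max(vapply(tsns, numInteractions, integer(1)))))
    methods::new("TSNSeries", source = network, tsns = tsns,
                 activeSets = active, threshold = threshold)
}
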