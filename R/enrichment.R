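# GO biological-process enrichment screening of functional modules via the
# standard upper-tail hypergeometric test over an annotated background.

#' Hypergeometric enrichment screen of functional modules
#'
#' For every module and every term annotated to at least one of its
#' members, computes the upper-tail hypergeometric probability of drawing
#' at least the observed number of term-annotated genes when sampling the
#' module's annotated members from the background. A module is significant
#' when its smallest p-value is below `cutoff` (0.001 by default, raw
#' p-values with no multiple-testing correction; Benjamini-Hochberg is
#' available via `correction = "bh"`, in which case the adjusted minimum
#' decides significance). Modules with no annotated member are flagged
#' unannotatable and excluded from the significant-fraction denominator
#' only when `dropUnannotatable = TRUE`.
#'
#' @param modules a [ModuleSet-class] (or a named list of protein-ID
#'   vectors).
#' @param ann an [AnnotationMap-class].
#' @param cutoff significance cutoff on the (possibly adjusted) minimum
#'   p-value (default 0.001).
#' @param correction `"none"` (default) or `"bh"`.
#' @param dropUnannotatable see above (default FALSE).
#' @return list with `rows` (one data.frame row per module/term pair with
#'   overlap >= 1: counts and p-value) and `summary` (per module: minimum
#'   p, `-log10` of it, significance and unannotatable flags, p-value band).
#' @export
enrichModules <- function(modules, ann, cutoff = 0.001,
                          correction = c("none", "bh"),
                          dropUnannotatable = FALSE) {
    correction <- match.arg(correction)
    stopifnot(methods::is(ann, "AnnotationMap"))
    protSets <- if (methods::is(modules, "ModuleSet")) moduleProteins(modules)
                else modules
    if (length(protSets) == 0) stop("no modules to screen", call. = FALSE)
    bg <- ann@background
    N <- length(bg)
    if (N == 0) stop("annotation background is empty", call. = FALSE)
    term2genes <- invertAnnotation(ann)
    termSize <- lengths(term2genes)

    rows <- list()
    minP <- setNames(rep(NA_real_, length(protSets)), names(protSets))
    for (mid in names(protSets)) {
        annotated <- intersect(protSets[[mid]], names(ann@gene2terms))
        nDraw <- length(annotated)
        if (nDraw == 0) next
        terms <- sort(unique(unlist(ann@gene2terms[annotated])))
        ov <- vapply(terms, function(tm)
            length(intersect(term2genes[[tm]], annotated)), integer(1))
        p <- phyper(ov - 1, termSize[terms], N - termSize[terms], nDraw,
                    lower.tail = FALSE)
        rows[[mid]] <- data.frame(
            module = mid, term = terms, overlap = ov,
            moduleAnnotated = nDraw, termSize = as.integer(termSize[terms]),
            background = N, p = as.numeric(p),
            row.names = NULL, stringsAsFactors = FALSE)
        minP[mid] <- min(p)
    }
    rows <- if (length(rows)) do.call(rbind, c(rows, make.row.names = FALSE))
            else data.frame(module = character(), term = character(),
                            overlap = integer(), moduleAnnotated = integer(),
                            termSize = integer(), background = integer(),
                            p = numeric())
    if (correction == "bh" && nrow(rows) > 0) {
        rows$pAdjusted <- p.adjust(rows$p, method = "BH")
        minP <- vapply(names(protSets), function(mid) {
            sel <- rows$module == mid
            if (!any(sel)) NA_real_ else min(rows$pAdjusted[sel])
        }, numeric(1))
    }
    unannotatable <- is.na(minP)
    significant <- !unannotatable & minP < cutoff
    summary <- data.frame(
        module = names(protSets),
        minP = as.numeric(minP),
        negLog10P = ifelse(unannotatable, NA_real_, -log10(minP)),
        significant = significant,
        unannotatable = unannotatable,
        band = pValueBand(minP),
        row.names = NULL, stringsAsFactors = FALSE)
    denom <- if (dropUnannotatable) sum(!unannotatable) else length(protSets)
    attr(summary, "fractionSignificant") <-
        if (denom > 0) sum(significant) / denom else NA_real_
    list(rows = rows, summary = summary)
}

#' Invert an annotation map to term-to-genes form
#'
#' @param ann an [AnnotationMap-class].
#' @return named list mapping each term to its annotated genes.
#' @export
invertAnnotation <- function(ann) {
    stopifnot(methods::is(ann, "AnnotationMap"))
    genes <- rep(names(ann@gene2terms), lengths(ann@gene2terms))
    split(genes, unlist(ann@gene2terms))
}

#' Band a p-value the way enrichment tables report it
#'
#' Bands: `<E-15`, `[E-15,E-10)`, `[E-10,E-5)`, `[E-5,0.001)`, `>=0.001`;
#' `NA` for unannotatable modules.
#'
#' @param p numeric vector of p-values.
#' @return character vector of band labels.
#' @export
pValueBand <- function(p) {
    out <- rep(NA_character_, length(p))
    ok <- !is.na(p)
    out[ok & p < 1e-15] <- "<E-15"
    out[ok & p >= 1e-15 & p < 1e-10] <- "E-15 to E-10"
    out[ok & p >= 1e-10 & p < 1e-5] <- "E-10 to E-5"
    out[ok & p >= 1e-5 & p < 1e-3] <- "E-5 to 0.001"
    out[ok & p >= 1e-3] <- ">=0.001"
    out
}

#' Summarise an enrichment screen
#'
#' Reports the number of modules, the fraction significant, the average
#' `-log10` minimum p-value over significant modules, and the fraction of
#' modules in each p-value band - the usual columns of a module-enrichment
#' comparison table.
#'
#' @param enr result of [enrichModules()].
#' @return one-row data.frame.
#' @export
enrichmentSummary <- function(enr) {
    s <- enr$summary
    sig <- s[which(s$significant), , drop = FALSE]
    bands <- c("<E-15", "E-15 to E-10", "E-10 to E-5", "E-5 to 0.001")
    bandFrac <- vapply(bands, function(b)
        if (nrow(s) > 0) sum(!is.na(s$band) & s$band == b & s$significant) / nrow(s)
        else NA_real_, numeric(1))
    out <- data.frame(nModules = nrow(s),
                      fractionSignificant = attr(s, "fractionSignificant"),
                      avgNegLog10P = if (nrow(sig)) mean(sig$negLog10P) else NA_real_)
    out[names(bandFrac)] <- bandFrac
    out
}
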