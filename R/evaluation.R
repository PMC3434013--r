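# Benchmarking predicted complexes against a gold standard: overlap score,
# threshold matching, sensitivity/specificity/f-measure, and complex
# frequency summaries.

#' Overlap score between a predicted and a known complex
#'
#' \eqn{OS(Pc, Kc) = |V_{Pc} \cap V_{Kc}|^2 / (|V_{Pc}| \cdot |V_{Kc}|)}:
#' the product of the two coverage fractions. Symmetric, 1 exactly for
#' identical sets, 0 exactly for disjoint ones. A predicted and a known
#' complex are conventionally declared a match when OS is at least some
#' threshold (0.2 is a common choice).
#'
#' @param pc,kc non-empty character vectors of member proteins.
#' @return overlap score in \[0, 1\].
#' @export
#' @examples
#' overlapScore(letters[1:7], c(letters[1:7], "x", "y"))  # 49/63 = 0.78
overlapScore <- function(pc, kc) {
    pc <- unique(pc); kc <- unique(kc)
    if (length(pc) == 0 || length(kc) == 0)
        stop("complex member sets must be non-empty", call. = FALSE)
    length(intersect(pc, kc))^2 / (length(pc) * length(kc))
}

#' Round an overlap score the way benchmark tables print it
#'
#' Two decimals, three for scores below 0.1 (so near-zero matches such as
#' 1/12 or 1/516 remain distinguishable from 0).
#'
#' @param os numeric vector of overlap scores.
#' @return rounded scores.
#' @export
osRound <- function(os) ifelse(os < 0.1, round(os, 3), round(os, 2))

#' Match predicted complexes against a gold standard
#'
#' Computes all pairwise overlap scores and counts, at threshold
#' `osThreshold`: TP, the number of predicted complexes whose best OS
#' against any known complex reaches the threshold; FP, the remaining
#' predicted complexes; FN, the number of known complexes reached by no
#' predicted complex. A predicted complex may match several known
#' complexes but is counted once. The per-known-complex best matches are
#' returned for benchmark-table style reports.
#'
#' @param predicted,known [ComplexCatalog-class] objects.
#' @param osThreshold match threshold in (0, 1] (default 0.2).
#' @return a [MatchResult-class].
#' @export
matchComplexes <- function(predicted, known, osThreshold = 0.2) {
    stopifnot(methods::is(predicted, "ComplexCatalog"),
              methods::is(known, "ComplexCatalog"))
    if (length(predicted) == 0 || length(known) == 0)
        stop("catalogues must be non-empty", call. = FALSE)
    if (osThreshold <= 0 || osThreshold > 1)
        stop("'osThreshold' must lie in (0, 1]", call. = FALSE)
    os <- matrix(0, length(predicted), length(known),
                 dimnames = list(predicted@ids, known@ids))
    for (i in seq_len(length(predicted)))
        for (j in seq_len(length(known)))
            os[i, j] <- overlapScore(predicted@members[[i]], known@members[[j]])
    bestPerPred <- apply(os, 1, max)
    bestPerKnown <- apply(os, 2, max)
    tp <- sum(bestPerPred >= osThreshold)
    fn <- sum(bestPerKnown < osThreshold)
    bestIdx <- apply(os, 2, which.max)
    bestMatches <- data.frame(
        known = known@ids,
        knownSize = lengths(known@members),
        predicted = predicted@ids[bestIdx],
        predictedSize = lengths(predicted@members)[bestIdx],
        overlap = vapply(seq_along(bestIdx), function(j)
            length(intersect(predicted@members[[bestIdx[j]]],
                             known@members[[j]])), integer(1)),
        os = bestPerKnown,
        osPrinted = osRound(bestPerKnown),
        row.names = NULL, stringsAsFactors = FALSE)
    matched <- bestMatches[bestMatches$os >= osThreshold, , drop = FALSE]
    pairs <- data.frame(predicted = matched$predicted, known = matched$known,
                        os = matched$os, row.names = NULL,
                        stringsAsFactors = FALSE)
    methods::new("MatchResult", osThreshold = osThreshold,
                 tp = as.integer(tp),
                 fp = as.integer(length(predicted) - tp),
                 fn = as.integer(fn), pairs = pairs, bestMatches = bestMatches)
}

#' Sensitivity, specificity and f-measure of a match result
#'
#' `Sn = TP / (TP + FN)`, `Sp = TP / (TP + FP)` and their harmonic mean
#' `f = 2 Sn Sp / (Sn + Sp)` (0 when TP is 0). Note the convention: TP and
#' FP count predicted complexes while FN counts known complexes, so Sn and
#' Sp mix the two sides; this follows the usual complex-benchmarking usage
#' rather than the contingency-table one.
#'
#' @param m a [MatchResult-class].
#' @return named numeric vector `c(Sn = ..., Sp = ..., f = ...)`.
#' @export
fMeasure <- function(m) {
    stopifnot(methods::is(m, "MatchResult"))
    if (m@tp + m@fn == 0)
        stop("Sn undefined: no known complexes counted (TP + FN = 0)",
             call. = FALSE)
    if (m@tp + m@fp == 0)
        stop("Sp undefined: no predicted complexes counted (TP + FP = 0)",
             call. = FALSE)
    sn <- m@tp / (m@tp + m@fn)
    sp <- m@tp / (m@tp + m@fp)
    f <- if (m@tp == 0) 0 else 2 * sn * sp / (sn + sp)
    c(Sn = sn, Sp = sp, f = f)
}

#' Frequency distribution of a complex catalogue
#'
#' Tabulates the complex frequencies f_T (number of TSNs each complex
#' appears in) and reports the two headline fractions: complexes seen in
#' exactly one TSN, and complexes seen in more than three.
#'
#' @param catalog a non-empty [ComplexCatalog-class].
#' @return list with elements `counts` (named integer vector, one entry per
#'   observed frequency), `fractionSingle` and `fractionAboveThree`.
#' @export
frequencyDistribution <- function(catalog) {
    stopifnot(methods::is(catalog, "ComplexCatalog"))
    if (length(catalog) == 0) stop("catalogue is empty", call. = FALSE)
    f <- catalog@frequency
    counts <- table(factor(f, levels = sort(unique(f))))
    list(counts = setNames(as.integer(counts), names(counts)),
         fractionSingle = mean(f == 1),
         fractionAboveThree = mean(f > 3))
}

#' Sweep the overlap-score threshold
#'
#' Convenience wrapper running [matchComplexes()] over a grid of
#' thresholds; the number of matched known complexes is non-increasing in
#' the threshold.
#'
#' @param predicted,known [ComplexCatalog-class] objects.
#' @param thresholds numeric vector of thresholds (default 0.1 to 1 in 0.1
#'   steps).
#' @return data.frame with columns `threshold`, `matchedKnown`, `tp`, `fp`,
#'   `fn`, `Sn`, `Sp`, `f`.
#' @export
osThresholdSweep <- function(predicted, known,
                             thresholds = seq(0.1, 1, by = 0.1)) {
    rows <- lapply(thresholds, function(th) {
        m <- matchComplexes(predicted, known, osThreshold = th)
        fm <- fMeasure(m)
        data.frame(threshold = th, matchedKnown = length(known) - m@fn,
                   tp = m@tp, fp = m@fp, fn = m@fn,
                   Sn = fm[["Sn"]], Sp = fm[["Sp"]], f = fm[["f"]])
    })
    do.call(rbind, rows)
}
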