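# Worked benchmark: overlap scores for the best-match examples shipped in
# inst/extdata, recomputed through the package's set arithmetic.

#' Recompute the worked benchmark overlap scores
#'
#' Loads the shipped gold-standard complexes and the best-match cluster
#' sizes (size of the best predicted cluster and number of shared members,
#' for static-network and dynamic-network clustering), reconstructs for
#' each row a predicted set with exactly the reported size and overlap
#' (shared members drawn from the known complex, remaining slots filled
#' with placeholder proteins), and scores it with [overlapScore()].
#'
#' @param knownPath path to the gold-standard catalogue; defaults to the
#'   file shipped with the package.
#' @param matchesPath path to the best-match size table; defaults to the
#'   shipped file.
#' @return data.frame with columns `known`, `network`, `pcSize`, `overlap`,
#'   `knownSize`, `os` and `osPrinted` (rounded as benchmark tables print
#'   it, see [osRound()]).
#' @export
benchmarkOverlapScores <- function(knownPath = NULL, matchesPath = NULL) {
    if (is.null(knownPath))
        knownPath <- system.file("extdata", "known_complexes_benchmark.tsv",
                                 package = "dynppin", mustWork = TRUE)
    if (is.null(matchesPath))
        matchesPath <- system.file("extdata", "benchmark_best_matches.tsv",
                                   package = "dynppin", mustWork = TRUE)
    known <- readComplexCatalog(knownPath)
    tab <- utils::read.table(matchesPath, sep = "\t", header = FALSE,
                             comment.char = "#", stringsAsFactors = FALSE,
                             col.names = c("known_id", "network", "pc_size",
                                           "overlap"))
    mem <- members(known)
    rows <- lapply(seq_len(nrow(tab)), function(i) {
        kc <- mem[[tab$known_id[i]]]
        if (is.null(kc)) stop("unknown complex: ", tab$known_id[i],
                              call. = FALSE)
        shared <- sort(kc)[seq_len(tab$overlap[i])]
        nFill <- tab$pc_size[i] - tab$overlap[i]
        pc <- c(shared, if (nFill > 0) sprintf("FILL%03d", seq_len(nFill)))
        os <- overlapScore(pc, kc)
        data.frame(known = tab$known_id[i], network = tab$network[i],
                   pcSize = tab$pc_size[i], overlap = tab$overlap[i],
                   knownSize = length(kc), os = os, osPrinted = osRound(os),
                   stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
}
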