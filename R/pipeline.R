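# End-to-end pipeline: read inputs, build the dynamic network, detect
# complexes, group them into modules, optionally benchmark and screen for
# enrichment, and leave a reproducible run manifest next to the outputs.

.stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
        stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
}

#' Run the full discovery pipeline
#'
#' Wires the stages end to end: expression filtering into TSNs, per-TSN
#' complex discovery, CIN construction, module extension, and (when a gold
#' standard or annotation map is given) overlap-score benchmarking and
#' enrichment screening. All outputs are plain TSV files plus a JSON
#' manifest recording the package version, every parameter and the MD5
#' checksum of every input, so a run can be reproduced exactly.
#'
#' @param ppi path to the PPI edge list.
#' @param expr path to the expression matrix.
#' @param outDir output directory (created if needed).
#' @param threshold expression activity threshold (default 0.7).
#' @param lambda cluster tightness ratio (default 1.0).
#' @param minSize minimum complex size s (default 3).
#' @param th CIN similarity threshold (default 0.5).
#' @param similarity similarity variant (default "squared").
#' @param sMin,sMax module protein-size bounds (defaults 3 and `Inf`).
#' @param weighted whether the edge list has a weight column.
#' @param unmeasured policy for unmeasured network proteins (see
#'   [buildTSNSeries()]).
#' @param known optional path to a gold-standard catalogue; triggers the
#'   benchmark report.
#' @param annotations optional path to a gene-to-term map; triggers the
#'   enrichment screen.
#' @param osThreshold overlap-score match threshold (default 0.2).
#' @param cutoff enrichment significance cutoff (default 0.001).
#' @param quiet suppress progress messages.
#' @return invisibly, a list with the in-memory results (`tsns`,
#'   `complexes`, `cin`, `modules`, optionally `match` and `enrichment`)
#'   and `files`, the paths written.
#' @export
runPipeline <- function(ppi, expr, outDir, threshold = 0.7, lambda = 1,
                        minSize = 3, th = 0.5, similarity = "squared",
                        sMin = 3, sMax = Inf, weighted = FALSE,
                        unmeasured = "inactive", known = NULL,
                        annotations = NULL, osThreshold = 0.2,
                        cutoff = 0.001, quiet = FALSE) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    inputs <- c(ppi = ppi, expr = expr, known = known, annotations = annotations)

    network <- .stage("io_formats", readPPIEdgelist(ppi, weighted = weighted,
                                                    quiet = quiet))
    # expression feeds only the dynamic-network stage; errors are named so
    exprS <- .stage("dynamic_network", readExpressionMatrix(expr))
    tsns <- .stage("dynamic_network",
                   buildTSNSeries(network, exprS, threshold = threshold,
                                  unmeasured = unmeasured, quiet = quiet))
    complexes <- .stage("complex_discovery",
                        discoverComplexes(tsns, lambda = lambda,
                                          minSize = minSize))
    files <- character(0)
    if (length(complexes) > 0) {
        writeClusters(complexes, file.path(outDir, "complexes.tsv"))
        files <- c(files, complexes = file.path(outDir, "complexes.tsv"))
    }
    cin <- NULL; modules <- NULL
    if (length(complexes) > 0) {
        cin <- .stage("module_discovery",
                      buildCIN(complexes, th = th, similarity = similarity))
        modules <- .stage("module_discovery",
                          detectModules(cin, complexes, sMin = sMin,
                                        sMax = sMax))
        writeClusters(modules, file.path(outDir, "modules.tsv"))
        files <- c(files, modules = file.path(outDir, "modules.tsv"))
    }
    match <- NULL
    if (!is.null(known) && length(complexes) > 0) {
        knownCat <- .stage("evaluation", readComplexCatalog(known))
        match <- .stage("evaluation",
                        matchComplexes(complexes, knownCat,
                                       osThreshold = osThreshold))
        utils::write.table(match@bestMatches,
                           file.path(outDir, "report.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, report = file.path(outDir, "report.tsv"))
    }
    enr <- NULL
    if (!is.null(annotations) && !is.null(modules) && length(modules) > 0) {
        ann <- .stage("evaluation", readAnnotationMap(annotations))
        enr <- .stage("evaluation",
                      enrichModules(modules, ann, cutoff = cutoff))
        utils::write.table(enr$summary, file.path(outDir, "enrichment.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        files <- c(files, enrichment = file.path(outDir, "enrichment.tsv"))
    }
    manifest <- list(
        package = "dynppin",
        version = as.character(utils::packageVersion("dynppin")),
        parameters = list(threshold = threshold, lambda = lambda,
                          minSize = minSize, th = th, similarity = similarity,
                          sMin = sMin,
                          sMax = if (is.finite(sMax)) sMax else "unlimited",
                          weighted = weighted, unmeasured = unmeasured,
                          osThreshold = osThreshold, cutoff = cutoff),
        inputs = lapply(inputs[!vapply(inputs, is.null, logical(1))],
                        function(f) list(path = f,
                                         md5 = unname(tools::md5sum(f)))),
        outputs = as.list(setNames(basename(files), names(files))))
    jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, manifest = file.path(outDir, "manifest.json"))
    if (!quiet)
        message(sprintf("pipeline finished: %d complexes, %d modules -> %s",
                        length(complexes),
                        if (is.null(modules)) 0L else length(modules), outDir))
    invisible(list(tsns = tsns, complexes = complexes, cin = cin,
                   modules = modules, match = match, enrichment = enr,
                   files = files))
}
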