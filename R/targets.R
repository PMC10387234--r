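#' Read per-source miRNA target-prediction lists
#'
#' Each source file is a TSV with header columns `mirna_id` and `gene`, one
#' predicted pair per row; duplicate pairs within a source are deduplicated.
#'
#' @param paths Named character vector `source -> TSV path`.
#' @return A `target_predictions` object (see [simulate_target_lists()]).
#' @export
read_target_lists <- function(paths) {
  if (is.null(names(paths)) || anyDuplicated(names(paths)))
    stop_arg("paths must be named by unique source labels")
  predictions <- list()
  for (src in names(paths)) {
    df <- utils::read.delim(paths[[src]], stringsAsFactors = FALSE)
    if (!identical(sort(names(df)), sort(c("mirna_id", "gene"))))
      stop_arg("file '%s' must have exactly columns mirna_id and gene (got: %s)",
               paths[[src]], paste(names(df), collapse = ", "))
    if (nrow(df) > 0L && any(!nzchar(df$gene)))
      stop_arg("file '%s' contains empty gene symbols", paths[[src]])
    predictions[[src]] <- lapply(split(df$gene, df$mirna_id),
                                 function(g) sort(unique(g)))
  }
  structure(list(sources = names(paths), predictions = predictions,
                 core = NULL),
            class = "target_predictions")
}

## All miRNA ids mentioned by any source.
all_pred_mirnas <- function(preds) {
  sort(unique(unlist(lapply(preds$predictions, names), use.names = FALSE)))
}

#' Consensus target genes across prediction sources
#'
#' A gene is kept as a target of a miRNA when at least `min_sources` sources
#' predict the pair; the default — all sources — is the strict intersection,
#' the combination considered most reliable when merging independent target
#' predictors.
#'
#' @param preds A `target_predictions` object.
#' @param min_sources Minimum number of agreeing sources, between 1 and the
#'   number of sources (default: all of them).
#' @return Named list `miRNA -> sorted character vector of consensus genes`.
#' @export
consensus_targets <- function(preds, min_sources = length(preds$sources)) {
  ns <- length(preds$sources)
  check_scalar_number(min_sources, "min_sources", lower = 1, upper = ns,
                      integer = TRUE)
  mirnas <- all_pred_mirnas(preds)
  out <- stats::setNames(vector("list", length(mirnas)), mirnas)
  for (m in mirnas) {
    gene_votes <- table(unlist(lapply(preds$predictions, function(p) p[[m]]),
                               use.names = FALSE))
    out[[m]] <- sort(names(gene_votes)[gene_votes >= min_sources])
  }
  out
}

#' Exclusive Venn-region counts of per-source target sets
#'
#' Counts, for every non-empty subset of sources, the genes predicted by
#' exactly that subset (union over miRNAs). Region counts sum to the size of
#' the union of all predictions.
#'
#' @param preds A `target_predictions` object with at most 6 sources.
#' @return `data.frame(sources, n)`: `sources` is the `+`-joined source
#'   subset label, `n` its exclusive gene count.
#' @export
venn_counts <- function(preds) {
  srcs <- preds$sources
  if (length(srcs) > 6L) stop_arg("venn_counts supports at most 6 sources")
  per_source <- lapply(preds$predictions[srcs], function(p)
    unique(unlist(p, use.names = FALSE)))
  universe <- unique(unlist(per_source, use.names = FALSE))
  membership <- vapply(per_source, function(g) universe %in% g,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  key <- apply(membership, 1L, function(row) paste(srcs[row], collapse = "+"))
  tab <- table(key)
  subsets <- unlist(lapply(seq_along(srcs), function(k)
    utils::combn(srcs, k, paste, collapse = "+", simplify = FALSE)))
  data.frame(sources = subsets,
             n = as.integer(ifelse(subsets %in% names(tab), tab[subsets], 0L)),
             stringsAsFactors = FALSE)
}

#' Build the miRNA-mRNA regulatory network of differential miRNAs
#'
#' Bipartite network linking each differential miRNA (direction `up` or
#' `down`; `ns` records are rejected) to its consensus target genes.
#'
#' @param de A differential-expression table from [de_table()] (or any
#'   data.frame with `mirna_id` and `direction`), already filtered to
#'   significant miRNAs.
#' @param consensus Named list `miRNA -> gene vector`, e.g. from
#'   [consensus_targets()]; miRNAs without an entry contribute no edges.
#' @return A list of class `regulatory_network`: `edges`
#'   (`data.frame(mirna_id, gene, mirna_direction)`, no duplicates) and
#'   `nodes` (`data.frame(node, type, direction)`).
#' @export
build_network <- function(de, consensus) {
  if (nrow(de) > 0L && any(de$direction == "ns"))
    stop_arg("build_network expects only differential records (direction != 'ns')")
  if (anyDuplicated(de$mirna_id)) stop_arg("duplicate miRNA ids in de table")
  edge_list <- lapply(seq_len(nrow(de)), function(i) {
    genes <- consensus[[de$mirna_id[i]]]
    if (length(genes) == 0L) return(NULL)
    data.frame(mirna_id = de$mirna_id[i], gene = sort(unique(genes)),
               mirna_direction = de$direction[i], stringsAsFactors = FALSE)
  })
  edges <- do.call(rbind, c(edge_list,
                            list(data.frame(mirna_id = character(0),
                                            gene = character(0),
                                            mirna_direction = character(0)))))
  rownames(edges) <- NULL
  genes <- unique(edges$gene)
  nodes <- rbind(
    data.frame(node = de$mirna_id, type = "miRNA", direction = de$direction,
               stringsAsFactors = FALSE),
    data.frame(node = genes, type = rep("gene", length(genes)),
               direction = rep(NA_character_, length(genes)),
               stringsAsFactors = FALSE)
  )
  rownames(nodes) <- NULL
  structure(list(edges = edges, nodes = nodes), class = "regulatory_network")
}

#' Write a regulatory network as edge-list TSV and SIF
#'
#' @param network A [build_network()] object.
#' @param tsv_path,sif_path Output paths (either may be `NULL` to skip). The
#'   SIF interaction label is the miRNA direction (`up`/`down`).
#' @return Invisibly, the written paths.
#' @export
write_network <- function(network, tsv_path = NULL, sif_path = NULL) {
  if (!is.null(tsv_path))
    utils::write.table(network$edges, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(sif_path)) {
    sif <- sprintf("%s\t%s\t%s", network$edges$mirna_id,
                   network$edges$mirna_direction, network$edges$gene)
    writeLines(sif, sif_path)
  }
  invisible(c(tsv = tsv_path, sif = sif_path))
}
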