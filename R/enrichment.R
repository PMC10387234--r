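#' Construct a term-to-gene annotation map
#'
#' @param annotations `data.frame` with one gene per row: columns `term_id`
#'   and `gene`, optionally `term_name` and `category` (the minimal
#'   two-column dialect is accepted).
#' @param background Optional gene universe ("genome background"); defaults
#'   to all genes appearing in the annotation. Every annotated gene must lie
#'   in the background.
#' @return A list of class `annotation_map`: `terms` (data.frame `term_id`,
#'   `term_name`, `category`, `size`), `genes` (list `term_id -> gene set`)
#'   and `background`.
#' @export
annotation_map <- function(annotations, background = NULL) {
  if (!all(c("term_id", "gene") %in% names(annotations)))
    stop_arg("annotations need columns term_id and gene")
  if (!"term_name" %in% names(annotations)) annotations$term_name <- annotations$term_id
  if (!"category" %in% names(annotations)) annotations$category <- NA_character_
  annotations <- unique(annotations[, c("term_id", "term_name", "category", "gene")])
  if (is.null(background))
    background <- sort(unique(annotations$gene))
  if (length(background) == 0L) stop_arg("empty background gene universe")
  outside <- setdiff(annotations$gene, background)
  if (length(outside) > 0L)
    stop_arg("%d annotated gene(s) are outside the background (e.g. %s)",
             length(outside), outside[1])
  genes <- lapply(split(annotations$gene, annotations$term_id),
                  function(g) sort(unique(g)))
  meta <- unique(annotations[, c("term_id", "term_name", "category")])
  if (anyDuplicated(meta$term_id))
    stop_arg("inconsistent term_name/category for a term_id")
  meta <- meta[order(meta$term_id), , drop = FALSE]
  meta$size <- lengths(genes)[meta$term_id]
  rownames(meta) <- NULL
  structure(list(terms = meta, genes = genes, background = background),
            class = "annotation_map")
}

#' Read an annotation map from TSV
#'
#' Accepts the four-column layout (`term_id`, `term_name`, `category`,
#' `gene`) or the minimal two-column dialect (`term_id`, `gene`), one gene
#' per row.
#'
#' @param path TSV path with a header row.
#' @param background Optional gene universe; see [annotation_map()].
#' @return An `annotation_map` object.
#' @export
read_annotations <- function(path, background = NULL) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("term_id", "gene") %in% names(df)))
    stop_arg("annotation file '%s' must contain columns term_id and gene", path)
  annotation_map(df, background = background)
}

#' Hypergeometric over-representation p-value
#'
#' Upper-tail probability `P(X >= k)` of drawing at least `k` genes of a term
#' of size `K` when sampling `n` genes without replacement from a background
#' of `N` genes.
#'
#' @param k Observed overlap between query and term.
#' @param K Term size within the background.
#' @param n Query size.
#' @param N Background ("genome") size.
#' @return The upper-tail p-value, in (0, 1].
#' @examples
#' hypergeom_pvalue(5, 5, 5, 10)  # 1 / choose(10, 5)
#' @export
hypergeom_pvalue <- function(k, K, n, N) {
  check_scalar_number(k, "k", lower = 0, integer = TRUE)
  check_scalar_number(K, "K", lower = 0, integer = TRUE)
  check_scalar_number(n, "n", lower = 0, integer = TRUE)
  check_scalar_number(N, "N", lower = 1, integer = TRUE)
  if (K > N || n > N || k > min(K, n))
    stop_arg("inconsistent counts: need k <= min(K, n) and K, n <= N")
  if (k == 0L) return(1)
  stats::phyper(k - 1L, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Term enrichment of a gene set by the hypergeometric test
#'
#' Tests each annotation term for over-representation in the query set
#' against the annotation's background, and adjusts p-values by
#' Benjamini-Hochberg across all tested terms. Query genes outside the
#' background are dropped with a warning (their number is recorded in the
#' `n_dropped` attribute).
#'
#' @param query Character vector of gene symbols.
#' @param annot An [annotation_map()] object.
#' @param min_term_size Smallest term size tested.
#' @return A `data.frame` sorted by `p` (ties by `term_id`) with columns
#'   `term_id`, `term_name`, `category`, `k` (overlap), `K` (term size), `n`
#'   (query size), `N` (background size), `p`, `q_bh`.
#' @export
enrich <- function(query, annot, min_term_size = 1L) {
  check_scalar_number(min_term_size, "min_term_size", lower = 1, integer = TRUE)
  query <- unique(query)
  dropped <- setdiff(query, annot$background)
  if (length(dropped) > 0L) {
    warning(sprintf("%d query gene(s) outside the background were dropped",
                    length(dropped)), call. = FALSE)
    query <- intersect(query, annot$background)
  }
  N <- length(annot$background)
  n <- length(query)
  keep <- annot$terms$size >= min_term_size
  terms <- annot$terms[keep, , drop = FALSE]
  k <- vapply(terms$term_id, function(t)
    length(intersect(annot$genes[[t]], query)), integer(1))
  p <- vapply(seq_len(nrow(terms)), function(i)
    hypergeom_pvalue(k[[i]], terms$size[[i]], n, N), numeric(1))
  out <- data.frame(
    term_id = terms$term_id, term_name = terms$term_name,
    category = terms$category,
    k = unname(k), K = terms$size, n = n, N = N,
    p = unname(p), q_bh = stats::p.adjust(p, method = "BH"),
    stringsAsFactors = FALSE
  )
  out <- out[order(out$p, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_dropped") <- length(dropped)
  out
}
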