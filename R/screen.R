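# Screen-level bookkeeping: reconciling independent scorer calls,
# tabulating the hit-gene table by phenotype class and cellular function,
# and hypergeometric functional enrichment against a user-supplied
# annotation table.

VALID_CALLS <- c("asymmetric", "symmetric", "unscorable")
VALID_CLASSES <- c("I", "II", "III")

#' Reconcile two independent scorers with a third tie-breaker
#'
#' Each strain is scored independently by two investigators; agreement
#' stands, disagreement is resolved by a third scorer when available and
#' is otherwise `unresolved`.
#'
#' @param calls_a,calls_b data.frames with columns `strain_id`, `call`
#'   (call in asymmetric/symmetric/unscorable).
#' @param calls_c optional third-scorer data.frame of the same shape;
#'   needs rows only for the disputed strains.
#' @return data.frame with `strain_id`, `scorer_a`, `scorer_b`,
#'   `scorer_c`, `consensus`; attributes `n_agreed`, `n_overridden`,
#'   `n_unresolved`.
#' @export
reconcile_scores <- function(calls_a, calls_b, calls_c = NULL) {
  check <- function(df, who) {
    if (!all(c("strain_id", "call") %in% names(df)))
      stopf("scorer %s table needs columns strain_id, call", who)
    if (anyDuplicated(df$strain_id))
      stopf("duplicate strain_id in scorer %s: %s", who,
            paste(unique(df$strain_id[duplicated(df$strain_id)]),
                  collapse = ", "))
    bad <- setdiff(unique(df$call), VALID_CALLS)
    if (length(bad))
      stopf("scorer %s has invalid calls: %s", who, paste(bad, collapse = ", "))
    df
  }
  calls_a <- check(calls_a, "A"); calls_b <- check(calls_b, "B")
  if (!is.null(calls_c)) calls_c <- check(calls_c, "C")
  ids <- sort(union(calls_a$strain_id, calls_b$strain_id))
  a <- calls_a$call[match(ids, calls_a$strain_id)]
  b <- calls_b$call[match(ids, calls_b$strain_id)]
  cc <- if (is.null(calls_c)) rep(NA_character_, length(ids))
        else calls_c$call[match(ids, calls_c$strain_id)]
  consensus <- ifelse(is.na(a) | is.na(b), "unresolved",
               ifelse(a == b, a, ifelse(is.na(cc), "unresolved", cc)))
  out <- data.frame(strain_id = ids, scorer_a = a, scorer_b = b,
                    scorer_c = cc, consensus = consensus)
  attr(out, "n_agreed") <- sum(!is.na(a) & !is.na(b) & a == b)
  attr(out, "n_overridden") <- sum(!is.na(a) & !is.na(b) & a != b & !is.na(cc))
  attr(out, "n_unresolved") <- sum(consensus == "unresolved")
  out
}

#' Load a screen hit-gene table
#'
#' Reads a TSV with columns `gene`, `alleles` (comma-separated allele
#' names), `class` (I/II/III phenotype class), `function`
#' (cellular-function category) and `mitotic_flag` (membership of the
#' mitotic cell-cycle annotation). The packaged transcription of the
#' published 81-gene hit table ships as
#' `system.file("extdata", "table1_genes.tsv", package = "asympart")`.
#'
#' @param path TSV path.
#' @return data.frame with one row per gene, `alleles` as a list column,
#'   plus `n_alleles`.
#' @export
load_gene_table <- function(path) {
  tab <- read_table(path)
  need <- c("gene", "alleles", "class", "function", "mitotic_flag")
  if (!all(need %in% names(tab)))
    stopf("gene table needs columns: %s", paste(need, collapse = ", "))
  if (nrow(tab) == 0) {
    tab$alleles <- list(); tab$n_alleles <- integer()
    return(tab)
  }
  bad <- which(!tab$class %in% VALID_CLASSES)
  if (length(bad))
    stopf("unknown class token '%s' at line %d of %s (expected I/II/III)",
          tab$class[bad[1]], bad[1] + 1L, path)
  dup <- unique(tab$gene[duplicated(tab$gene)])
  if (length(dup))
    stopf("duplicate gene symbols: %s", paste(dup, collapse = ", "))
  alleles <- lapply(strsplit(tab$alleles, ","), trimws)
  if (any(lengths(alleles) < 1L)) stopf("every gene needs >= 1 allele")
  tab$alleles <- alleles
  tab$mitotic_flag <- as.logical(tab$mitotic_flag)
  tab$n_alleles <- lengths(alleles)
  tab
}

#' Tabulate a hit-gene table by phenotype class and function
#'
#' Gene counts and integer percentages (rounded half-up, the printed
#' convention) per phenotype class and per cellular-function category,
#' plus allele totals. Counts are conserved: class and function counts
#' each sum to the number of genes.
#'
#' @param records a [load_gene_table()] data.frame.
#' @return list of class `class_summary`: `classes` and `functions`
#'   data.frames, `n_genes`, `n_alleles`.
#' @export
tabulate_classes <- function(records) {
  if (nrow(records) < 1) stopf("need >= 1 gene record")
  n <- nrow(records)
  cls <- data.frame(class = VALID_CLASSES)
  cls$n_genes <- vapply(cls$class, function(k) sum(records$class == k),
                        integer(1))
  cls$pct_genes <- round_half_up(100 * cls$n_genes / n)
  cls$n_alleles <- vapply(cls$class, function(k)
    sum(records$n_alleles[records$class == k]), integer(1))
  fun <- sort(unique(records[["function"]]))
  fns <- data.frame(category = fun)
  fns$n_genes <- vapply(fun, function(k)
    sum(records[["function"]] == k), integer(1))
  fns$pct_genes <- round_half_up(100 * fns$n_genes / n)
  fns <- fns[order(-fns$n_genes, fns$category), ]
  rownames(fns) <- NULL
  structure(list(classes = cls, functions = fns, n_genes = n,
                 n_alleles = sum(records$n_alleles)),
            class = "class_summary")
}

#' @export
print.class_summary <- function(x, ...) {
  cat(sprintf("class_summary: %d genes, %d alleles\n", x$n_genes,
              x$n_alleles))
  print(x$classes); print(x$functions)
  invisible(x)
}

#' Functional enrichment of screen hits against a background collection
#'
#' For each functional category: `k` hits among the `n` hit genes versus
#' `K` annotated genes among the `N`-gene background; fold enrichment
#' `(k/n) / (K/N)` and a one-sided (enrichment) Fisher's exact p-value.
#' The background stands in for the screened collection's annotation — a
#' plain gene-to-category table; no live ontology is consulted. Hits
#' absent from the background are dropped with a warning.
#'
#' @param hit_genes character vector of hit gene symbols.
#' @param background_annotation data.frame with columns `gene`,
#'   `category`; one row per gene/category membership.
#' @return data.frame sorted by p-value: `category`, `k`, `n`, `K`, `N`,
#'   `fold_enrichment`, `p_value`.
#' @export
functional_enrichment <- function(hit_genes, background_annotation) {
  if (!all(c("gene", "category") %in% names(background_annotation)))
    stopf("background_annotation needs columns gene, category")
  if (nrow(background_annotation) == 0) stopf("empty background annotation")
  bg_genes <- unique(background_annotation$gene)
  hit_genes <- unique(hit_genes)
  missing <- setdiff(hit_genes, bg_genes)
  if (length(missing)) {
    warning(sprintf("%d hit gene(s) absent from background dropped: %s",
                    length(missing), paste(missing, collapse = ", ")),
            call. = FALSE)
    hit_genes <- setdiff(hit_genes, missing)
  }
  n <- length(hit_genes)
  N <- length(bg_genes)
  if (n == 0) stopf("no hit genes overlap the background")
  cats <- sort(unique(background_annotation$category))
  out <- lapply(cats, function(cat) {
    in_cat <- unique(background_annotation$gene[
      background_annotation$category == cat])
    K <- length(in_cat)
    k <- length(intersect(hit_genes, in_cat))
    fold <- (k / n) / (K / N)
    tab <- matrix(c(k, n - k, K - k, N - n - (K - k)), 2, byrow = TRUE)
    p <- stats::fisher.test(tab, alternative = "greater")$p.value
    data.frame(category = cat, k = k, n = n, K = K, N = N,
               fold_enrichment = fold, p_value = p)
  })
  out <- do.call(rbind, out)
  out <- out[order(out$p_value, out$category), ]
  rownames(out) <- NULL
  out
}

#' Screen coverage percentage
#'
#' Percent of the collection successfully scored, rounded half-up to an
#' integer (the printed convention).
#'
#' @param scored,total strain counts, `0 <= scored <= total`.
#' @return integer percentage.
#' @export
screen_coverage <- function(scored, total) {
  if (total < 1 || scored < 0 || scored > total)
    stopf("need 0 <= scored <= total and total >= 1")
  round_half_up(100 * scored / total)
}
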