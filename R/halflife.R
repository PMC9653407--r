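#' Join a gene set against an mRNA half-life table
#'
#' Inner join on case-normalized gene id, reporting how many genes matched
#' and the mean half-life of the matched set.
#'
#' @param genes character vector of gene ids.
#' @param table data.frame with columns gene and half_life_hours (see
#'   \code{\link{read_halflife}}).
#' @return list: \code{matched} (data.frame gene, half_life_hours),
#'   \code{n_matched}, \code{n_unmatched}, \code{mean_half_life},
#'   \code{status} (\code{"ok"} or \code{"empty_join"}).
#' @export
#' @examples
#' join_half_lives(c("A", "B"),
#'                 data.frame(gene = "A", half_life_hours = 1))
join_half_lives <- function(genes, table) {
  if (length(genes) == 0) stop("empty gene set")
  idx <- match(toupper(genes), toupper(table$gene))
  matched <- data.frame(gene = genes[!is.na(idx)],
                        half_life_hours =
                          table$half_life_hours[idx[!is.na(idx)]],
                        stringsAsFactors = FALSE)
  n_matched <- nrow(matched)
  list(matched = matched,
       n_matched = n_matched,
       n_unmatched = length(genes) - n_matched,
       mean_half_life = if (n_matched) mean(matched$half_life_hours)
                        else NA_real_,
       status = if (n_matched) "ok" else "empty_join")
}

#' Welch two-sample t-test of module vs background mRNA half-lives
#'
#' Two-sided Welch (unequal-variance) t-test with Welch-Satterthwaite degrees
#' of freedom, comparing the half-lives of module genes against background
#' genes, plus the group summaries used for the companion boxplot.  When both
#' groups are constant the test is degenerate: equal means give t = 0, p = 1
#' by convention; unequal constant means give p = 0.
#'
#' @param module_hl,background_hl numeric vectors of half-lives in hours,
#'   each with at least 2 values.
#' @return list: t, df, p, n_module, n_background, mean_module,
#'   mean_background, median_module, median_background.
#' @export
welch_halflife_test <- function(module_hl, background_hl) {
  if (length(module_hl) < 2 || length(background_hl) < 2)
    stop("each group needs at least 2 half-life values")
  v1 <- var(module_hl); v2 <- var(background_hl)
  if (v1 == 0 && v2 == 0) {
    eq <- mean(module_hl) == mean(background_hl)
    t_stat <- if (eq) 0 else sign(mean(module_hl) - mean(background_hl)) * Inf
    res <- list(t = t_stat,
                df = length(module_hl) + length(background_hl) - 2,
                p = if (eq) 1 else 0)
  } else {
    ht <- t.test(module_hl, background_hl, var.equal = FALSE)
    res <- list(t = unname(ht$statistic), df = unname(ht$parameter),
                p = ht$p.value)
  }
  c(res, list(n_module = length(module_hl),
              n_background = length(background_hl),
              mean_module = mean(module_hl),
              mean_background = mean(background_hl),
              median_module = median(module_hl),
              median_background = median(background_hl)))
}

#' Module vs background half-life analysis
#'
#' Convenience wrapper: joins module genes and background genes against the
#' half-life table and runs \code{\link{welch_halflife_test}}.  The
#' background set is, by default, the half-life-table genes not in the module
#' set; \code{background = "tested"} restricts it to a supplied vector of
#' analysed genes instead.
#'
#' @param module_genes character vector of module gene ids.
#' @param halflife data.frame with gene and half_life_hours.
#' @param background_genes optional explicit background gene set; default is
#'   every half-life-table gene not in \code{module_genes}.
#' @return list with elements \code{join} (the module join report) and
#'   \code{test} (the Welch test result), or status \code{"skipped"} when the
#'   join is empty.
#' @export
halflife_module_test <- function(module_genes, halflife,
                                 background_genes = NULL) {
  jn <- join_half_lives(module_genes, halflife)
  if (jn$status == "empty_join")
    return(list(join = jn, test = NULL, status = "skipped"))
  if (is.null(background_genes))
    background_genes <- setdiff(halflife$gene, module_genes)
  bg <- join_half_lives(background_genes, halflife)
  if (bg$n_matched < 2 || jn$n_matched < 2)
    return(list(join = jn, test = NULL, status = "skipped"))
  list(join = jn,
       test = welch_halflife_test(jn$matched$half_life_hours,
                                  bg$matched$half_life_hours),
       status = "ok")
}
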