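## Group comparison layer: one-way ANOVA, Tukey HSD pairwise comparisons
## and the figure-caption star convention.

.checkGroupTable <- function(groups) {
    if (!is.list(groups) || is.null(names(groups)) || any(names(groups) == ""))
        stop("groups must be a named list of numeric vectors")
    if (length(groups) < 2L) stop("need at least 2 groups")
    if (any(vapply(groups, length, integer(1)) < 2L))
        stop("every group needs at least 2 values")
    if (any(!vapply(groups, is.numeric, logical(1))))
        stop("group values must be numeric")
    vals <- unlist(groups, use.names = FALSE)
    if (any(!is.finite(vals))) stop("group values must be finite")
    if (var(vals) == 0)
        stop("degenerate input: all values identical (no variance to decompose)")
    invisible(groups)
}

.stackGroups <- function(groups) {
    data.frame(
        value = unlist(groups, use.names = FALSE),
        group = factor(rep(names(groups), vapply(groups, length, integer(1))),
                       levels = names(groups)))
}

#' One-way analysis of variance across groups
#'
#' Classical between/within variance decomposition over a named list of
#' per-group value vectors (e.g. a fitted parameter by week of
#' differentiation).
#'
#' @param groups named list (>= 2 entries) of numeric vectors (length >= 2)
#' @return List with elements \code{F} and \code{p}.
#' @examples
#' oneWayAnova(list(a = c(1, 2, 3), b = c(2, 3, 4)))
#' @export
oneWayAnova <- function(groups) {
    .checkGroupTable(groups)
    tab <- anova(aov(value ~ group, data = .stackGroups(groups)))
    list(F = tab[["F value"]][1], p = tab[["Pr(>F)"]][1])
}

#' Tukey honest-significant-difference pairwise comparisons
#'
#' All pairwise group comparisons with studentized-range-adjusted p-values
#' (Tukey-Kramer for unequal group sizes), annotated with the star
#' convention of \code{\link{starLabel}}.
#'
#' @param groups named list (>= 2 entries) of numeric vectors (length >= 2)
#' @return A \code{data.frame} with one row per unordered pair:
#'   \code{group_a}, \code{group_b}, \code{mean_diff} (b minus a),
#'   \code{p_adj}, \code{stars}.
#' @examples
#' tukeyHsd(list(a = rnorm(5), b = rnorm(5) + 3, c = rnorm(5)))
#' @export
tukeyHsd <- function(groups) {
    .checkGroupTable(groups)
    hsd <- TukeyHSD(aov(value ~ group, data = .stackGroups(groups)))$group
    pair <- strsplit(rownames(hsd), "-", fixed = TRUE)
    out <- data.frame(
        group_a = vapply(pair, `[`, character(1), 2L),
        group_b = vapply(pair, `[`, character(1), 1L),
        mean_diff = unname(hsd[, "diff"]),
        p_adj = unname(hsd[, "p adj"]))
    out$stars <- starLabel(out$p_adj)
    rownames(out) <- NULL
    out
}

#' Significance star labels
#'
#' The figure-caption convention: \code{***} for p < 0.001, \code{**} for
#' p < 0.01, \code{*} for p < 0.05, else \code{"ns"}.  Inequalities are
#' strict, so p = 0.05 exactly is "ns".
#'
#' @param p p-value(s) in [0, 1]
#' @return Character vector of labels.
#' @examples
#' starLabel(c(0.04, 0.5, 0.0005))
#' @export
starLabel <- function(p) {
    if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
        stop("p must lie in [0, 1]")
    ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns")))
}

#' Pairwise comparisons of fitted parameters across groups
#'
#' Runs \code{\link{tukeyHsd}} per parameter on accepted fit results,
#' producing the long-format comparison table.
#'
#' @param results fit results (as from \code{\link{fitSpectra}}), with a
#'   \code{group} column
#' @param parameters result columns to compare
#' @return A \code{data.frame} with columns \code{parameter},
#'   \code{group_a}, \code{group_b}, \code{mean_diff}, \code{p_adj},
#'   \code{stars}.
#' @export
compareGroups <- function(results,
                          parameters = c("mem_rel_permittivity",
                              "mem_conductivity_S_per_m",
                              "int_conductivity_S_per_m",
                              "co_first_hz", "co_second_hz")) {
    res <- results[!results$rejected, , drop = FALSE]
    parameters <- intersect(parameters, colnames(res))
    out <- lapply(parameters, function(pn) {
        v <- res[[pn]]
        ok <- is.finite(v)
        groups <- split(v[ok], as.character(res$group[ok]))
        groups <- groups[vapply(groups, length, integer(1)) >= 2L]
        if (length(groups) < 2L) return(NULL)
        cbind(parameter = pn, tukeyHsd(groups))
    })
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
}
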