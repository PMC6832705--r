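# Group statistics used throughout the workflow: mean +/- SE summaries,
# one-way ANOVA, Tukey HSD (Tukey-Kramer for unbalanced designs) with a
# compact letter display, and report assembly.

# normalize input to a data.frame(group, value)
.as_group_table <- function(table) {
  if (is.data.frame(table)) {
    stopifnot(all(c("group", "value") %in% names(table)))
    df <- data.frame(group = as.character(table$group), value = table$value)
  } else if (is.list(table)) {
    df <- do.call(rbind, lapply(names(table), function(g)
      data.frame(group = g, value = as.numeric(table[[g]]))))
  } else {
    stop("table must be a data.frame(group, value) or a named list")
  }
  df <- df[is.finite(df$value), ]
  if (length(unique(df$group)) < 2) stop("need at least 2 groups")
  df
}

#' One-way analysis of variance
#'
#' Classical fixed-effects one-way ANOVA (no Welch correction): F from the
#' between/within sum-of-squares decomposition with df = (k - 1, N - k).
#'
#' @param table data.frame with columns `group`, `value`, or a named list of
#'   numeric vectors. Every group needs n >= 2.
#' @return Object of class `anova_result`: `f`, `df_between`, `df_within`,
#'   `p`.
#' @export
one_way_anova <- function(table) {
  df <- .as_group_table(table)
  ns <- table(df$group)
  if (any(ns < 2))
    stop("every group needs at least 2 observations (offending: ",
         paste(names(ns)[ns < 2], collapse = ", "), ")")
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  tab <- summary(fit)[[1]]
  structure(list(f = tab["group", "F value"],
                 df_between = as.integer(tab["group", "Df"]),
                 df_within = as.integer(tab["Residuals", "Df"]),
                 p = tab["group", "Pr(>F)"]),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("one-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$f, x$p))
  invisible(x)
}

#' Tukey HSD post-hoc comparisons with compact letter display
#'
#' All pairwise comparisons with studentized-range adjusted p-values
#' (Tukey-Kramer under unequal group sizes), and per-group letters such that
#' two groups share a letter iff they are not significantly different at
#' `alpha`.
#'
#' @param table As in [one_way_anova()].
#' @param alpha Significance level for the letter display.
#' @return Object of class `tukey_result`: data.frame `pairs` (`group_i`,
#'   `group_j`, `diff`, `lwr`, `upr`, `p_adj`), named character `letters`,
#'   `alpha`.
#' @export
tukey_hsd <- function(table, alpha = 0.05) {
  df <- .as_group_table(table)
  ns <- table(df$group)
  if (any(ns < 2))
    stop("every group needs at least 2 observations")
  df$group <- factor(df$group)
  fit <- stats::aov(value ~ group, data = df)
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$group
  nm <- strsplit(rownames(tk), "-", fixed = TRUE)
  pairs <- data.frame(group_i = vapply(nm, `[`, "", 1),
                      group_j = vapply(nm, `[`, "", 2),
                      diff = tk[, "diff"], lwr = tk[, "lwr"],
                      upr = tk[, "upr"], p_adj = tk[, "p adj"],
                      row.names = NULL)
  means <- tapply(df$value, df$group, mean)
  letters <- .cld_letters(levels(df$group), pairs, alpha, means)
  structure(list(pairs = pairs, letters = letters, alpha = alpha),
            class = "tukey_result")
}

# Compact letter display: groups sharing a letter are pairwise
# non-significant. Letters are the maximal cliques of the non-significance
# graph, ordered by decreasing group mean.
.cld_letters <- function(groups, pairs, alpha, means) {
  k <- length(groups)
  adj <- matrix(FALSE, k, k, dimnames = list(groups, groups))
  diag(adj) <- TRUE
  for (r in seq_len(nrow(pairs))) {
    ns <- pairs$p_adj[r] > alpha
    adj[pairs$group_i[r], pairs$group_j[r]] <- ns
    adj[pairs$group_j[r], pairs$group_i[r]] <- ns
  }
  # enumerate maximal cliques (group counts are small)
  cliques <- list()
  expand <- function(current, candidates) {
    extended <- FALSE
    for (v in candidates) {
      if (all(adj[v, current])) {
        extended <- TRUE
        expand(c(current, v), candidates[candidates > v])
      }
    }
    if (!extended) {
      # maximal iff no vertex outside extends it
      outside <- setdiff(seq_len(k), current)
      if (!any(vapply(outside, function(v) all(adj[v, current]), logical(1))))
        cliques[[length(cliques) + 1]] <<- sort(current)
    }
  }
  for (v in seq_len(k)) expand(v, seq_len(k)[seq_len(k) > v])
  cliques <- unique(cliques)
  # order cliques by the best (highest) mean they contain
  ord <- order(vapply(cliques, function(cl) -max(means[groups[cl]]),
                      numeric(1)))
  cliques <- cliques[ord]
  # assign letters a, b, c, ... in clique order
  letters <- stats::setNames(rep("", k), groups)
  for (i in seq_along(cliques)) {
    letters[cliques[[i]]] <- paste0(letters[cliques[[i]]], base::letters[i])
  }
  letters
}

#' @export
print.tukey_result <- function(x, ...) {
  cat("Tukey HSD (alpha =", x$alpha, ")\n")
  print(x$pairs, digits = 4)
  cat("letters:", paste(names(x$letters), x$letters, sep = "=",
                        collapse = "  "), "\n")
  invisible(x)
}

#' Per-group mean, standard error and n
#'
#' @param table As in [one_way_anova()] (single-observation groups are
#'   allowed; their SE is `NA`).
#' @return data.frame with `group`, `mean`, `se`, `n`.
#' @export
summarize_groups <- function(table) {
  if (is.data.frame(table)) {
    df <- data.frame(group = as.character(table$group), value = table$value)
  } else {
    df <- do.call(rbind, lapply(names(table), function(g)
      data.frame(group = g, value = as.numeric(table[[g]]))))
  }
  df <- df[is.finite(df$value), ]
  out <- do.call(rbind, lapply(split(df$value, df$group), function(x) {
    data.frame(mean = mean(x),
               se = if (length(x) >= 2) stats::sd(x) / sqrt(length(x))
                    else NA_real_,
               n = length(x))
  }))
  data.frame(group = rownames(out), out, row.names = NULL)
}

#' Assemble the analysis report
#'
#' Collects the electrophysiology, dose-response and imaging summaries into
#' one structured document with provenance; sections whose inputs are
#' missing are marked "not run". The report serializes deterministically
#' (no timestamps), so identical inputs give byte-identical JSON.
#'
#' @param ephys,fits,mgv Section content (lists/data.frames) or `NULL`.
#' @param seed Seed used for the run.
#' @param config The pipeline configuration used (hashed into provenance).
#' @return Object of class `analysis_report` (a list).
#' @export
build_report <- function(ephys = NULL, fits = NULL, mgv = NULL,
                         seed = NA_integer_, config = NULL) {
  section <- function(x) if (is.null(x)) list(status = "not run")
                         else list(status = "ok", results = x)
  structure(list(
    provenance = list(package = "dumpharm",
                      version = as.character(utils::packageVersion("dumpharm")),
                      seed = seed,
                      config_hash = if (is.null(config)) NA_character_
                                    else rlang::hash(config)),
    rsh = section(ephys),
    dose_response = section(fits),
    mgv = section(mgv)),
    class = "analysis_report")
}

#' Write a report as pretty JSON
#'
#' @param report An `analysis_report`.
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null", dataframe = "rows")
  invisible(path)
}
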