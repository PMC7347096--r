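#' Report tables over contextual zone statistics
#'
#' Builds the comparison tables of a shoot-structure study from labelled
#' segmentations and the sequence metadata:
#'
#' * `zone_metamers` — per-group mean/SD of zone lengths, metamers per shoot
#'   and associated flower buds per shoot, with Kruskal-Wallis omnibus
#'   p-values and pairwise Wilcoxon compact letters across groups;
#' * `occurrence` — per-group frequency of occurrence of each zone with a
#'   Pearson chi-squared comparison of the occurrence proportions;
#' * `correlations` — per-group Spearman rank correlations between zone
#'   lengths and between each zone and the total metamer count, with the
#'   significance limits below which coefficients are reported "ns".
#'
#' With a single group, letter assignment and omnibus tests are skipped (and
#' logged). A zone absent from a group appears with occurrence 0 and missing
#' length statistics; when tables are written to disk, missing cells are
#' rendered as `-`.
#'
#' @param seg A labelled `segmentation`.
#' @param seqs The matching `shoot_sequences` tibble.
#' @param group_by Metadata columns defining the comparison groups
#'   (default `c("genotype", "year")`).
#' @param alpha Significance level for letters and limits.
#' @param out_dir Optional directory; when given, each table is written as a
#'   TSV file (`zone_metamers.tsv`, `occurrence.tsv`, `correlations.tsv`).
#' @return A named list of tibbles, invisibly when writing to `out_dir`.
#' @export
summary_tables <- function(seg, seqs, group_by = c("genotype", "year"),
                           alpha = 0.05, out_dir = NULL) {
  if (!"zone" %in% names(seg)) {
    abort("Segmentation has no `zone` column; run label_zones() first.")
  }
  meta <- shoot_summaries(seqs)
  group_by <- intersect(group_by, names(meta))
  if (length(group_by) == 0) abort("No usable grouping columns.")
  segm <- dplyr::left_join(seg, meta, by = "shoot_id")
  glab <- function(df) {
    if (length(group_by) == 1) as.character(df[[group_by]])
    else do.call(paste, c(df[group_by], sep = ":"))
  }
  meta$group <- glab(meta)
  segm$group <- glab(segm)
  groups <- sort(unique(meta$group))
  single <- length(groups) < 2
  if (single) inform("Single group: omnibus tests and letters skipped.")
  zl <- unname(ZONE_LABELS)

  compare_var <- function(df, value) {
    # df: group + value column, one row per observation
    base <- df |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(n = dplyr::n(), mean = mean(.data[[value]]),
                       sd = sd(.data[[value]]), .groups = "drop")
    base <- dplyr::left_join(tibble::tibble(group = groups), base, by = "group")
    base$n[is.na(base$n)] <- 0L
    present <- base$group[base$n > 0]
    if (!single && length(present) >= 2 &&
        sum(base$n[base$group %in% present]) >= 3) {
      cmp <- pairwise_wilcoxon_letters(df[df$group %in% present, ],
                                       value, "group", alpha = alpha)
      base$letters <- cmp$groups$letters[match(base$group, cmp$groups$group)]
      base$kw_p <- if (!is.null(cmp$test)) cmp$test$p_value else NA_real_
    } else {
      base$letters <- NA_character_
      base$kw_p <- NA_real_
    }
    base
  }

  zone_rows <- lapply(zl, function(z) {
    d <- segm[as.character(segm$zone) == z, c("group", "length")]
    names(d) <- c("group", "value")
    out <- compare_var(d, "value")
    out$variable <- paste0(z, "_zone_metamers")
    out
  })
  shoot_rows <- lapply(c("n_metamers", "n_assoc_flowers"), function(v) {
    d <- meta[, c("group", v)]
    out <- compare_var(d, v)
    out$variable <- paste0(v, "_per_shoot")
    out
  })
  zone_metamers <- dplyr::bind_rows(c(zone_rows, shoot_rows)) |>
    dplyr::select("variable", "group", "n", "mean", "sd", "letters", "kw_p")

  occ <- contextual_parameters(seg, seqs, group_by = group_by)$occurrence
  occ$group <- glab(occ)
  occurrence <- occ |>
    dplyr::select("group", "zone", "n_shoots", "occurrence")
  occurrence$chi2_p <- NA_real_
  if (!single) {
    for (z in zl) {
      oz <- occurrence[occurrence$zone == z, ]
      present <- round(oz$occurrence * oz$n_shoots)
      tab <- cbind(present = present, absent = oz$n_shoots - present)
      p <- tryCatch(proportion_chi2(tab)$p_value, error = function(e) NA_real_)
      occurrence$chi2_p[occurrence$zone == z] <- p
    }
  }

  correlations <- dplyr::bind_rows(lapply(groups, function(gr) {
    ids <- meta$shoot_id[meta$group == gr]
    wide <- tibble::tibble(shoot_id = ids)
    for (z in zl) {
      lenz <- segm$length[as.character(segm$zone) == z]
      idz <- segm$shoot_id[as.character(segm$zone) == z]
      wide[[z]] <- ifelse(wide$shoot_id %in% idz,
                          lenz[match(wide$shoot_id, idz)], 0L)
    }
    wide$total <- meta$n_metamers[match(wide$shoot_id, meta$shoot_id)]
    pairs <- rbind(t(utils::combn(zl, 2)),
                   cbind(zl, "total"))
    dplyr::bind_rows(apply(pairs, 1, function(pr) {
      res <- tryCatch(
        spearman_with_limits(wide[[pr[1]]], wide[[pr[2]]], alpha = alpha,
                             label = paste(pr[1], "vs", pr[2])),
        error = function(e) tibble::tibble(
          pair = paste(pr[1], "vs", pr[2]), n = length(ids),
          rho = NA_real_, limit = NA_real_, significant = NA
        )
      )
      res$group <- gr
      res
    }))
  })) |>
    dplyr::select("group", "pair", "n", "rho", "limit", "significant")

  tables <- list(zone_metamers = zone_metamers, occurrence = occurrence,
                 correlations = correlations)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(tables)) {
      readr::write_tsv(tables[[nm]], file.path(out_dir, paste0(nm, ".tsv")),
                       na = "-", progress = FALSE)
    }
    return(invisible(tables))
  }
  tables
}

#' Compare survival (or any occurrence) proportions across groups
#'
#' Generic proportion comparison: given per-group counts of successes
#' (e.g. shoots still alive) and totals, reports per-group proportions and a
#' Pearson chi-squared test of homogeneity.
#'
#' @param data A data frame.
#' @param group Name of the group column.
#' @param alive Name of the success-count column.
#' @param total Name of the total-count column.
#' @return A list: `proportions` tibble (group, alive, total, proportion) and
#'   one-row `test` tibble from [proportion_chi2()].
#' @export
proportion_table <- function(data, group, alive, total) {
  a <- as.integer(data[[alive]])
  t_ <- as.integer(data[[total]])
  if (any(a > t_)) abort("Success counts exceed totals.")
  props <- tibble::tibble(
    group = as.character(data[[group]]), alive = a, total = t_,
    proportion = a / t_
  )
  test <- proportion_chi2(cbind(alive = a, dead = t_ - a))
  list(proportions = props, test = test)
}
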