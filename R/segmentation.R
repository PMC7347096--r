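#' Restore the most probable state sequence (optimal segmentation)
#'
#' For each shoot, computes the globally most probable (state, duration) path
#' under the fitted model and the absorbing end-state convention, by a
#' semi-Markov Viterbi dynamic program. The restored path partitions the shoot
#' into contiguous zones with strictly increasing state indices (left-right).
#' Ties between equal-probability paths are broken deterministically: at every
#' dynamic-programming cell candidates are scanned by increasing zone duration
#' then increasing predecessor state index and replaced only on strict
#' improvement, so the restoration prefers shorter current durations and
#' lower state indices.
#'
#' @param seqs A `shoot_sequences` tibble.
#' @param m A validated `hsmc_model`.
#' @return A `segmentation` tibble, one row per zone: `shoot_id`, `state`,
#'   `start_rank`, `length`, `path_logprob` (log-probability of the whole
#'   restored path, repeated across its segments).
#' @export
restore_states <- function(seqs, m) {
  lp <- model_logparams(m)
  shoots <- split_shoots(seqs)
  out <- lapply(shoots, function(s) {
    v <- hsmc_viterbi_cpp(lp$logpi, lp$logA, lp$logd,
                          emission_logprob(m, s$fate, s$flower))
    if (!is.finite(v$logprob)) {
      logB <- emission_logprob(m, s$fate, s$flower)
      bad <- which(apply(logB, 2, function(col) all(!is.finite(col))))[1]
      abort(paste0(
        "Shoot ", s$shoot_id, " has log-likelihood -Inf; node ",
        if (is.na(bad)) "(none individually impossible)" else bad,
        " has probability zero in every state."
      ))
    }
    tibble::tibble(shoot_id = s$shoot_id, state = v$state,
                   start_rank = v$start, length = v$length,
                   path_logprob = v$logprob)
  })
  seg <- dplyr::bind_rows(out)
  assert_partition(seg, seqs)
  class(seg) <- c("segmentation", class(tibble::tibble()))
  seg
}

# Every segmentation must exactly partition its sequence: contiguous segments
# from rank 1, lengths >= 1, strictly increasing states.
assert_partition <- function(seg, seqs) {
  lens <- table(seqs$shoot_id)
  for (sid in unique(seg$shoot_id)) {
    g <- seg[seg$shoot_id == sid, ]
    g <- g[order(g$start_rank), ]
    if (g$start_rank[1] != 1 || any(g$length < 1) ||
        any(diff(g$state) <= 0) ||
        !identical(g$start_rank, cumsum(c(1L, utils::head(g$length, -1)))) ||
        sum(g$length) != as.integer(lens[[sid]])) {
      abort(paste0("Internal error: segmentation of shoot ", sid,
                   " does not partition the sequence."))
    }
  }
  invisible(seg)
}

#' Map model states to zone labels
#'
#' Each transient state is labelled by the argmax of its bud-fate emission
#' distribution: latent-dominated states are `basal`, floral-dominated
#' `median`, vegetative-dominated `distal`.
#'
#' @param m An `hsmc_model`.
#' @param strict Error when two states share a fate argmax (default `TRUE`);
#'   with `FALSE` duplicate labels are returned as-is (useful for synthetic
#'   truth bookkeeping).
#' @return Character vector of zone labels, one per transient state.
#' @export
zone_mapping <- function(m, strict = TRUE) {
  fates <- vapply(m$b, function(e) FATE_LEVELS[which.max(e$fate)], "")
  labels <- unname(ZONE_LABELS[fates])
  if (strict && anyDuplicated(labels) > 0) {
    abort(paste0(
      "States ", paste(which(labels %in% labels[duplicated(labels)]),
                       collapse = ", "),
      " share a bud-fate argmax; zones cannot be labelled automatically. ",
      "Supply a manual state-to-zone mapping."
    ))
  }
  labels
}

#' Attach zone labels to a segmentation
#'
#' Tags every restored segment as `basal`, `median` or `distal` using
#' [zone_mapping()]. States absent from a shoot's path simply yield no segment
#' of that label: the median and/or distal zone may be skipped.
#'
#' @param seg A `segmentation` tibble from [restore_states()].
#' @param m The `hsmc_model` used for restoration.
#' @return The segmentation with a `zone` factor column
#'   (levels basal, median, distal).
#' @export
label_zones <- function(seg, m) {
  map <- zone_mapping(m)
  seg$zone <- factor(map[seg$state], levels = unname(ZONE_LABELS))
  seg
}

#' Posterior state probabilities per node
#'
#' Forward-backward smoothing probabilities `P(state at node t | shoot)`,
#' exposed for diagnostics alongside the optimal restoration.
#'
#' @inheritParams restore_states
#' @return A tibble: `shoot_id`, `node_rank`, `state`, `prob`.
#' @export
posterior_states <- function(seqs, m) {
  lp <- model_logparams(m)
  shoots <- split_shoots(seqs)
  dplyr::bind_rows(lapply(shoots, function(s) {
    e <- hsmc_estep_cpp(lp$logpi, lp$logA, lp$logd,
                        emission_logprob(m, s$fate, s$flower))
    Ti <- length(s$fate)
    tibble::tibble(
      shoot_id = s$shoot_id,
      node_rank = rep(seq_len(Ti), each = m$K),
      state = rep(seq_len(m$K), Ti),
      prob = as.vector(e$gamma)
    )
  }))
}

#' Contextual zone statistics from restored segmentations
#'
#' Extracts, per group of shoots (e.g. per genotype, year or shoot type), the
#' empirical "contextual" quantities the segmentation implies: the frequency
#' of occurrence of each zone (fraction of shoots containing it), the
#' empirical transition probabilities between successive zones including the
#' transition to shoot end, per-zone mean and SD of zone length in metamers,
#' and per-shoot means of metamer and associated-flower-bud counts. All
#' quantities are computed from the restored (optimal) segmentations, not
#' from model parameters.
#'
#' @param seg A labelled `segmentation` (see [label_zones()]).
#' @param seqs The matching `shoot_sequences` tibble.
#' @param group_by Character vector of metadata columns to stratify by
#'   (subset of `genotype`, `year`, `shoot_type`); `character(0)` pools all
#'   shoots.
#' @return An object of class `contextual_summary`: a list of tibbles
#'   `occurrence`, `transitions`, `zone_lengths`, `shoots`, each carrying the
#'   grouping columns.
#' @export
contextual_parameters <- function(seg, seqs, group_by = character(0)) {
  if (!"zone" %in% names(seg)) {
    abort("Segmentation has no `zone` column; run label_zones() first.")
  }
  meta <- shoot_summaries(seqs)
  bad <- setdiff(group_by, names(meta))
  if (length(bad) > 0) {
    abort(paste0("Unknown grouping key(s): ", paste(bad, collapse = ", ")))
  }
  if (nrow(seg) == 0) abort("Empty segmentation.")
  segm <- dplyr::left_join(seg, meta, by = "shoot_id")
  zl <- unname(ZONE_LABELS)

  grp <- function(df) dplyr::group_by(df, dplyr::across(dplyr::all_of(group_by)))

  occurrence <- segm |>
    dplyr::distinct(.data$shoot_id, .data$zone, .keep_all = TRUE) |>
    grp() |>
    dplyr::group_modify(function(d, ...) {
      n <- length(unique(d$shoot_id))
      tibble::tibble(
        zone = factor(zl, levels = zl),
        n_shoots = n,
        occurrence = unname(vapply(zl, function(z)
          length(unique(d$shoot_id[d$zone == z])) / n, 0))
      )
    }) |>
    dplyr::ungroup()

  transitions <- segm |>
    grp() |>
    dplyr::group_modify(function(d, ...) {
      steps <- d |>
        dplyr::arrange(.data$shoot_id, .data$start_rank) |>
        dplyr::group_by(.data$shoot_id) |>
        dplyr::reframe(from = as.character(.data$zone),
                       to = c(as.character(.data$zone)[-1], "end"))
      steps |>
        dplyr::count(.data$from, .data$to) |>
        dplyr::group_by(.data$from) |>
        dplyr::mutate(prob = .data$n / sum(.data$n)) |>
        dplyr::ungroup()
    }) |>
    dplyr::ungroup()

  zone_lengths <- segm |>
    grp() |>
    dplyr::group_modify(function(d, ...) {
      d |>
        dplyr::group_by(.data$zone, .drop = FALSE) |>
        dplyr::summarise(n = dplyr::n(),
                         mean_metamers = mean(.data$length),
                         sd_metamers = sd(.data$length), .groups = "drop")
    }) |>
    dplyr::ungroup()

  shoots <- meta |>
    grp() |>
    dplyr::summarise(n_shoots = dplyr::n(),
                     mean_metamers = mean(.data$n_metamers),
                     sd_metamers = sd(.data$n_metamers),
                     mean_assoc_flowers = mean(.data$n_assoc_flowers),
                     .groups = "drop")

  structure(list(occurrence = occurrence, transitions = transitions,
                 zone_lengths = zone_lengths, shoots = shoots,
                 group_by = group_by),
            class = "contextual_summary")
}

#' @export
print.contextual_summary <- function(x, ...) {
  cat("Contextual zone statistics",
      if (length(x$group_by) > 0)
        paste0("by ", paste(x$group_by, collapse = " x ")) else "(pooled)",
      "\n\nZone occurrence:\n")
  print(x$occurrence)
  cat("\nZone-to-zone transition frequencies:\n")
  print(x$transitions)
  cat("\nZone lengths (metamers):\n")
  print(x$zone_lengths)
  cat("\nPer-shoot summaries:\n")
  print(x$shoots)
  invisible(x)
}
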