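#' Classify shoots into length classes
#'
#' Shoots are classified by their total length into short (SS, up to 2 cm),
#' medium (MS, above 2 up to 10 cm) and long (LS, above 10 cm) shoots. The
#' breakpoints sit exactly at 2.0 and 10.0 cm, both belonging to the lower
#' class.
#'
#' @param length_cm Numeric vector of positive shoot lengths in centimetres.
#' @return A factor with levels `SS`, `MS`, `LS`.
#' @examples
#' classify_shoot_type(c(1.5, 2, 2.1, 10, 10.5))
#' @export
classify_shoot_type <- function(length_cm) {
  if (!is.numeric(length_cm)) {
    abort("`length_cm` must be numeric.")
  }
  if (anyNA(length_cm) || any(length_cm <= 0)) {
    abort("`length_cm` must be positive and non-missing for classification.")
  }
  cut(length_cm, breaks = c(0, 2, 10, Inf), labels = c("SS", "MS", "LS"),
      right = TRUE)
}

#' Assemble a shoot-sequence table
#'
#' A shoot-sequence table holds one row per metamer (node) of every shoot,
#' ordered base to tip: `shoot_id`, `genotype`, `year`, `node_rank` (1 = base),
#' `bud_fate` (central bud fate, one of `L`, `V`, `F`), `assoc_flowers`
#' (associated flower-bud class `0`, `1`, `2+`), and per-shoot metadata
#' `length_cm` (optional) and `fruit_count` (optional, carried but never
#' modelled). Integer associated-flower counts of 2 or more are pooled into
#' the `2+` class; the raw integer is preserved in `assoc_flowers_n` when
#' counts were supplied.
#'
#' @param df A data frame with at least `shoot_id`, `genotype`, `year`,
#'   `node_rank`, `bud_fate`, `assoc_flowers`.
#' @param drop_incomplete Drop (with a warning) shoots that fail validation
#'   instead of erroring. Default `FALSE`.
#' @return A validated `shoot_sequences` tibble.
#' @export
as_shoot_sequences <- function(df, drop_incomplete = FALSE) {
  required <- c("shoot_id", "genotype", "year", "node_rank", "bud_fate",
                "assoc_flowers")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing required columns: ",
                 paste(missing_cols, collapse = ", ")))
  }
  out <- tibble::as_tibble(df)
  out$shoot_id <- as.character(out$shoot_id)
  out$genotype <- as.character(out$genotype)
  out$node_rank <- as.integer(out$node_rank)
  out$bud_fate <- as.character(out$bud_fate)
  flw <- out$assoc_flowers
  if (is.numeric(flw)) {
    if (!"assoc_flowers_n" %in% names(out)) out$assoc_flowers_n <- as.integer(flw)
    out$assoc_flowers <- ifelse(flw >= 2, "2+", as.character(as.integer(flw)))
  } else {
    out$assoc_flowers <- as.character(flw)
  }
  if (!"length_cm" %in% names(out)) out$length_cm <- NA_real_
  if (!"fruit_count" %in% names(out)) out$fruit_count <- NA_integer_

  out <- validate_shoot_sequences(out, drop_incomplete = drop_incomplete)
  class(out) <- c("shoot_sequences", class(tibble::tibble()))
  out
}

validate_shoot_sequences <- function(df, drop_incomplete = FALSE) {
  line_of <- function(idx) paste0("row ", idx)
  problems <- character()
  bad_shoots <- character()
  flag <- function(shoot, msg) {
    problems <<- c(problems, msg)
    bad_shoots <<- c(bad_shoots, shoot)
  }

  bad_fate <- which(!(df$bud_fate %in% FATE_LEVELS) | is.na(df$bud_fate))
  for (i in bad_fate) {
    flag(df$shoot_id[i], paste0("shoot ", df$shoot_id[i], ", ", line_of(i),
                                ": unknown bud fate code '", df$bud_fate[i], "'"))
  }
  bad_flw <- which(!(df$assoc_flowers %in% FLOWER_LEVELS) | is.na(df$assoc_flowers))
  for (i in bad_flw) {
    flag(df$shoot_id[i], paste0("shoot ", df$shoot_id[i], ", ", line_of(i),
                                ": unknown associated-flower class '",
                                df$assoc_flowers[i], "'"))
  }

  key <- paste(df$shoot_id, df$node_rank)
  dup <- which(duplicated(key))
  for (i in dup) {
    flag(df$shoot_id[i], paste0("shoot ", df$shoot_id[i], ", ", line_of(i),
                                ": duplicate node rank ", df$node_rank[i]))
  }

  for (sid in unique(df$shoot_id)) {
    rk <- sort(df$node_rank[df$shoot_id == sid])
    if (length(rk) < 2) {
      flag(sid, paste0("shoot ", sid, ": sequence shorter than 2 metamers"))
    } else if (!identical(as.integer(rk), seq_len(length(rk)))) {
      flag(sid, paste0("shoot ", sid,
                       ": node ranks not contiguous from 1 (found ",
                       paste(utils::head(rk, 5), collapse = ","), " ...)"))
    }
  }

  if (length(problems) > 0) {
    if (drop_incomplete) {
      bad <- unique(bad_shoots)
      warn(paste0("Dropping ", length(bad), " invalid shoot(s): ",
                  paste(problems, collapse = "; ")))
      df <- df[!(df$shoot_id %in% bad), , drop = FALSE]
      if (nrow(df) == 0) abort("All shoots were dropped during validation.")
    } else {
      abort(paste0("Invalid shoot sequences: ",
                   paste(problems, collapse = "; ")))
    }
  }
  dplyr::arrange(df, .data$shoot_id, .data$node_rank)
}

#' Read shoot sequences from a TSV file
#'
#' The sequence file format is UTF-8 tab-separated text with a header row and
#' one row per metamer; required columns `shoot_id`, `genotype`, `year`,
#' `node_rank`, `bud_fate`, `assoc_flowers`, optional `length_cm`,
#' `fruit_count`, `assoc_flowers_n`.
#'
#' @param path File path (or connection) to read.
#' @inheritParams as_shoot_sequences
#' @return A `shoot_sequences` tibble.
#' @export
read_shoot_sequences <- function(path, drop_incomplete = FALSE) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    shoot_id = readr::col_character(),
    genotype = readr::col_character(),
    year = readr::col_character(),
    node_rank = readr::col_integer(),
    bud_fate = readr::col_character(),
    assoc_flowers = readr::col_character(),
    .default = readr::col_guess()
  ), progress = FALSE)
  as_shoot_sequences(df, drop_incomplete = drop_incomplete)
}

#' Write shoot sequences to a TSV file
#'
#' Writing then re-reading reproduces the table field-for-field
#' (`parse(write(S)) == S`).
#'
#' @param seqs A `shoot_sequences` tibble.
#' @param path Output file path.
#' @return `seqs`, invisibly.
#' @export
write_shoot_sequences <- function(seqs, path) {
  keep <- c("shoot_id", "genotype", "year", "node_rank", "bud_fate",
            "assoc_flowers", "length_cm", "fruit_count", "assoc_flowers_n")
  df <- seqs[, intersect(keep, names(seqs)), drop = FALSE]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(seqs)
}

# Split a shoot_sequences tibble into per-shoot lists used by the numeric core:
# integer-coded fate/flower observations plus per-shoot metadata.
split_shoots <- function(seqs) {
  col <- function(nm, default = NA) {
    if (nm %in% names(seqs)) seqs[[nm]] else rep(default, nrow(seqs))
  }
  genotype <- col("genotype")
  year <- col("year")
  length_cm <- col("length_cm", NA_real_)
  idx <- split(seq_len(nrow(seqs)), seqs$shoot_id)
  lapply(idx, function(i) {
    i <- i[order(seqs$node_rank[i])]
    list(
      shoot_id = seqs$shoot_id[i[1]],
      genotype = genotype[i[1]],
      year = year[i[1]],
      length_cm = length_cm[i[1]],
      fate = match(seqs$bud_fate[i], FATE_LEVELS),
      flower = match(seqs$assoc_flowers[i], FLOWER_LEVELS)
    )
  })
}

#' Per-shoot metadata summary
#'
#' Collapses a shoot-sequence table to one row per shoot with its metadata,
#' metamer count, derived shoot type (when `length_cm` is present) and the
#' number of associated flower buds per shoot. The flower-bud count scores
#' class `1` as one bud and the pooled class `2+` as two buds, its observable
#' lower bound, unless raw counts (`assoc_flowers_n`) are available.
#'
#' @param seqs A `shoot_sequences` tibble.
#' @return One row per shoot: `shoot_id`, `genotype`, `year`, `length_cm`,
#'   `shoot_type`, `n_metamers`, `n_assoc_flowers`.
#' @export
shoot_summaries <- function(seqs) {
  has_raw <- "assoc_flowers_n" %in% names(seqs) && !all(is.na(seqs$assoc_flowers_n))
  out <- seqs |>
    dplyr::group_by(.data$shoot_id, .data$genotype, .data$year) |>
    dplyr::summarise(
      length_cm = .data$length_cm[1],
      n_metamers = dplyr::n(),
      n_assoc_flowers = if (has_raw) sum(.data$assoc_flowers_n) else
        sum((.data$assoc_flowers == "1") + 2 * (.data$assoc_flowers == "2+")),
      .groups = "drop"
    )
  out$shoot_type <- factor(NA_character_, levels = c("SS", "MS", "LS"))
  ok <- !is.na(out$length_cm) & out$length_cm > 0
  if (any(!ok)) {
    inform(paste0(sum(!ok), " shoot(s) without usable length_cm; ",
                  "shoot-type stratified statistics will skip them."))
  }
  out$shoot_type[ok] <- classify_shoot_type(out$length_cm[ok])
  out
}
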