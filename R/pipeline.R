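#' Run the full precursor-discovery pipeline
#'
#' Executes the stages of the homology-based protocol in order: scan the
#' database for mature-miRNA matches, extract flanked candidate windows,
#' screen against an optional exclusion database, fold each window (built-in
#' model, or externally supplied structures), validate each candidate
#' against the nine hairpin criteria, and collapse accepted candidates
#' sharing more than `config$precursor_identity` percent identity (over the
#' trimmed precursor region) into single loci. Per-stage in/out counts are
#' recorded. Output is deterministic for fixed inputs and configuration.
#'
#' @param db Sequence tibble from [read_fasta()].
#' @param mature Mature catalog from [read_mature_fasta()].
#' @param config A [mircane_config()].
#' @param exclusion_db Optional sequence tibble of non-miRNA RNAs.
#' @param folds Optional named list of `mircane_fold` objects keyed by
#'   window id (e.g. parsed from an external folding run); windows without
#'   an entry fall back to the built-in model.
#' @return A `mircane_precursor_result`: list with `report` (per-candidate
#'   criterion tibble plus `accepted`/`locus` columns), `loci` (one row per
#'   accepted locus), `hits`, `windows`, `log` (stage counts), `config` and
#'   `config_hash`.
#' @export
run_precursor_pipeline <- function(db, mature, config = mircane_config(),
                                   exclusion_db = NULL, folds = NULL) {
  if (!is.data.frame(mature) || nrow(mature) == 0) {
    abort("precursor pipeline: empty mature catalog")
  }
  log <- list()
  note <- function(stage, n_in, n_out) {
    log[[length(log) + 1]] <<- tibble(stage = stage, n_in = n_in,
                                      n_out = n_out)
  }

  hits <- with_stage("scan", scan_mirna(db, mature,
                                        max_edits = config$max_edits,
                                        seed_len = config$seed_len))
  note("scan", nrow(db), nrow(hits))

  windows <- with_stage("window",
                        extract_windows(db, hits, flank = config$flank))
  note("window", nrow(hits), nrow(windows))

  screened <- with_stage("exclusion",
                         exclusion_screen(windows, exclusion_db,
                                          max_edits = config$max_edits))
  note("exclusion", nrow(windows), nrow(screened))

  reports <- vector("list", nrow(screened))
  energy_model <- character(nrow(screened))
  for (i in seq_len(nrow(screened))) {
    w <- screened[i, ]
    fold <- folds[[w$window_id]] %||% NULL
    if (is.null(fold)) {
      fold <- with_stage("fold", fold_rna(w$residues,
                                          min_loop = config$min_loop,
                                          weights = config$fold_weights),
                         w$window_id)
      energy_model[i] <- "builtin"
    } else {
      energy_model[i] <- fold$source
    }
    q <- mature[mature$family == w$family, ][1, ]
    reports[[i]] <- with_stage("check", check_hairpin(w, fold, q, config),
                               w$window_id)
  }
  report <- bind_rows(reports)
  if (nrow(report) > 0) report$energy_model <- energy_model
  n_acc <- if (nrow(report) > 0) sum(report$verdict == "accept") else 0L
  note("check", nrow(screened), n_acc)

  # Collapse accepted candidates into loci in two steps: candidates whose
  # windows overlap on the same database record are one genomic locus (a
  # mature-arm hit, its star-arm hit on the opposite strand, and hits from
  # near-identical catalog entries all describe the same stem-loop); locus
  # representatives are then clustered by global identity over the trimmed
  # precursor, mirroring the published > 95%-identity redundancy rule.
  loci <- tibble(locus = integer(), representative = character(),
                 family = character(), n_members = integer())
  if (n_acc > 0) {
    acc <- report[report$verdict == "accept", ]
    acc_w <- screened[match(acc$window_id, screened$window_id), ]
    grp <- overlap_groups(acc_w$db_id, acc_w$window_start,
                          acc_w$window_end)
    # representative per genomic locus: best-paired, then leftmost
    rep_idx <- vapply(split(seq_len(nrow(acc)), grp), function(idx) {
      o <- order(-acc$paired_count[idx], acc$mismatch_count[idx],
                 acc_w$window_start[idx], acc$family[idx])
      idx[o[1]]
    }, integer(1))
    trimmed <- tibble(
      id = acc$window_id[rep_idx],
      residues = substr(acc_w$residues[rep_idx],
                        acc$trimmed_start[rep_idx],
                        acc$trimmed_end[rep_idx])
    )
    cl <- cluster_sequences(trimmed, threshold = config$precursor_identity,
                            strict = TRUE)
    loci <- tibble(
      locus = cl$cluster,
      representative = cl$representative,
      family = acc$family[match(cl$representative, acc$window_id)],
      n_members = NA_integer_
    )
    report$locus <- NA_integer_
    group_of_rep <- grp[rep_idx][match(cl$representative,
                                       acc$window_id[rep_idx])]
    for (k in seq_len(nrow(cl))) {
      groups_k <- group_of_rep[match(cl$members[[k]],
                                     acc$window_id[rep_idx])]
      member_windows <- acc$window_id[grp %in% groups_k]
      report$locus[report$window_id %in% member_windows] <- cl$cluster[k]
      loci$n_members[k] <- length(member_windows)
    }
  }
  note("collapse", n_acc, nrow(loci))

  near_miss_log(report, hits)

  structure(
    list(report = report, loci = loci, hits = hits, windows = screened,
         log = bind_rows(log), config = config,
         config_hash = config_hash(config)),
    class = "mircane_precursor_result"
  )
}

# single-linkage grouping of intervals by overlap within each record id
overlap_groups <- function(ids, starts, ends) {
  n <- length(ids)
  grp <- integer(n)
  g <- 0L
  for (rec in unique(ids)) {
    idx <- which(ids == rec)
    o <- idx[order(starts[idx], ends[idx])]
    hi <- -Inf
    for (i in o) {
      if (starts[i] > hi) g <- g + 1L
      grp[i] <- g
      hi <- max(hi, ends[i])
    }
  }
  grp
}

with_stage <- function(stage, expr, id = NULL) {
  tryCatch(expr, error = function(e) {
    abort(paste0("pipeline stage '", stage, "' failed",
                 if (!is.null(id)) paste0(" on ", id) else "",
                 ": ", conditionMessage(e)))
  })
}

# candidates matching a catalog sequence near-perfectly but failing the
# structural validation get flagged for manual review
near_miss_log <- function(report, hits) {
  if (nrow(report) == 0) return(invisible(NULL))
  rej <- report[report$verdict == "reject", ]
  for (i in seq_len(nrow(rej))) {
    h <- hits[hits$db_id == rej$db_id[i] & hits$family == rej$family[i], ]
    if (nrow(h) > 0 && min(h$edit_total) == 0) {
      inform(paste0("near-miss: ", rej$window_id[i],
                    " matches ", rej$family[i],
                    " exactly but fails criteria [",
                    rej$failed_criteria[i], "]"))
    }
  }
  invisible(NULL)
}

#' Run the target-prediction pipeline
#'
#' Thin orchestration around [scan_targets()] with stage logging and a
#' result object carrying the resolved configuration.
#'
#' @inheritParams run_precursor_pipeline
#' @param transcripts Sequence tibble of candidate messages.
#' @return A `mircane_target_result`: list with `hits`, `log`, `config`,
#'   `config_hash`.
#' @export
run_target_pipeline <- function(mature, transcripts,
                                config = mircane_config()) {
  if (!is.data.frame(mature) || nrow(mature) == 0) {
    abort("target pipeline: empty mature catalog")
  }
  hits <- scan_targets(mature, transcripts, config)
  log <- tibble(
    stage = c("scan_targets"),
    n_in = nrow(transcripts),
    n_out = nrow(hits)
  )
  structure(
    list(hits = hits, log = log, config = config,
         config_hash = config_hash(config)),
    class = "mircane_target_result"
  )
}

#' @export
print.mircane_precursor_result <- function(x, ...) {
  cat("<mircane_precursor_result> config ", x$config_hash, "\n", sep = "")
  print(x$log)
  if (nrow(x$loci) > 0) {
    fams <- table(x$loci$family)
    cat("accepted loci by family:\n")
    for (f in names(fams)) cat("  ", f, ": ", fams[[f]], "\n", sep = "")
    acc <- x$report[x$report$verdict == "accept", ]
    cat(sprintf("MFEI of accepted candidates: mean %.2f (sd %.2f)\n",
                mean(acc$mfei), sd(acc$mfei)))
  } else {
    cat("no accepted loci\n")
  }
  invisible(x)
}

#' @export
print.mircane_target_result <- function(x, ...) {
  cat("<mircane_target_result> config ", x$config_hash, "\n", sep = "")
  cat(nrow(x$hits), "accepted target sites\n")
  invisible(x)
}

#' @rdname run_precursor_pipeline
#' @param x A `mircane_precursor_result`.
#' @param ... Unused.
#' @export
tidy.mircane_precursor_result <- function(x, ...) {
  x$report
}

#' @rdname run_precursor_pipeline
#' @export
glance.mircane_precursor_result <- function(x, ...) {
  acc <- x$report[x$report$verdict == "accept", ]
  tibble(
    n_records = x$log$n_in[x$log$stage == "scan"],
    n_hits = nrow(x$hits),
    n_windows = nrow(x$windows),
    n_accepted = nrow(acc),
    n_loci = nrow(x$loci),
    mfei_mean = if (nrow(acc) > 0) mean(acc$mfei) else NA_real_,
    mfei_sd = if (nrow(acc) > 1) sd(acc$mfei) else NA_real_,
    config_hash = x$config_hash
  )
}

#' @rdname run_target_pipeline
#' @param x A `mircane_target_result`.
#' @param ... Unused.
#' @export
tidy.mircane_target_result <- function(x, ...) {
  x$hits
}

#' @rdname run_target_pipeline
#' @export
glance.mircane_target_result <- function(x, ...) {
  tibble(
    n_transcripts = x$log$n_in[1],
    n_targets = nrow(x$hits),
    n_families = length(unique(x$hits$family)),
    score_mean = if (nrow(x$hits) > 0) mean(x$hits$score) else NA_real_,
    config_hash = x$config_hash
  )
}
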