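# The repeated-split evaluation harness: per-class shuffles, 45/5 splits,
# balanced frame training, and evaluation at frame, frame-group and
# vocalization granularity; plus the dual-network protocol and the
# threshold-sensitivity sweeps.

#' Split plan for the repeated evaluation protocol
#'
#' Five repeats of a per-class 45/5 train/test split (90%/10%) by default:
#' each repeat shuffles the recordings of every class with its own seed and
#' takes the first `per_class_train` for training, the next
#' `per_class_test` for testing.
#'
#' @param n_repeats number of shuffled repeats.
#' @param per_class_train,per_class_test recordings per class in each split.
#' @param seed master seed from which the per-repeat shuffle seeds derive.
#' @return a `split_plan` list.
#' @export
split_plan <- function(n_repeats = 5, per_class_train = 45, per_class_test = 5,
                       seed = 1) {
  if (per_class_test < 1) stopf("`per_class_test` must be at least 1")
  if (per_class_train < 1) stopf("`per_class_train` must be at least 1")
  structure(
    list(n_repeats = as.integer(n_repeats),
         per_class_train = as.integer(per_class_train),
         per_class_test = as.integer(per_class_test),
         seeds = derive_seeds(seed, n_repeats)),
    class = "split_plan"
  )
}

# One per-class shuffled split of recording ids.
split_recordings <- function(dataset, plan, repeat_seed) {
  counts <- table(dataset$species)
  need <- plan$per_class_train + plan$per_class_test
  if (any(counts < need)) {
    bad <- names(counts)[counts < need]
    stopf("Insufficient recordings for a %d/%d split: %s",
          plan$per_class_train, plan$per_class_test,
          paste(sprintf("%s=%d", bad, counts[bad]), collapse = ", "))
  }
  with_seed(repeat_seed, {
    dataset |>
      dplyr::group_by(.data$species) |>
      dplyr::slice_sample(prop = 1) |>
      dplyr::mutate(.rank = dplyr::row_number()) |>
      dplyr::ungroup() |>
      dplyr::mutate(role = dplyr::case_when(
        .data$.rank <= plan$per_class_train ~ "train",
        .data$.rank <= plan$per_class_train + plan$per_class_test ~ "test",
        TRUE ~ "unused")) |>
      dplyr::select("source_id", "species", "role")
  })
}

#' Run the repeated-split classification protocol
#'
#' For each repeat: shuffle recordings per class, split
#' `per_class_train`/`per_class_test`, train the network on the training
#' features (balanced per class for frame modes), and evaluate. Frame modes
#' (P2/P4) are scored at frame granularity, at every frame-group size in
#' `group_sizes` (majority voting within recordings), and at vocalization
#' granularity (mode over all of a recording's frames). Vocalization modes
#' (P1/P3) are scored per recording directly.
#'
#' @param dataset tibble with `species`, `source_id` and `clip` list-column
#'   (see [generate_dataset()] / [load_audio_dir()]).
#' @param mode feature formation mode (`"P1"`–`"P4"`).
#' @param params a [feature_params()].
#' @param plan a [split_plan()].
#' @param config an [mlp_config()]; its seed is re-derived per repeat.
#' @param group_sizes frame-group sizes for majority voting (frame modes).
#' @return a `protocol_report`: `repeats` (per-repeat metric rows),
#'   `summary` (metrics averaged over repeats with SDs), `reports` (the
#'   underlying `eval_report`s), plus `mode`, `params`, `plan`.
#' @export
run_protocol <- function(dataset, mode = "P4", params = feature_params(),
                         plan = split_plan(), config = mlp_config(),
                         group_sizes = c(1, 5, 10, 25)) {
  stopifnot(is.data.frame(dataset), all(c("species", "source_id", "clip") %in% names(dataset)))
  features <- build_feature_table(dataset, mode = mode, params = params)
  frame_mode <- mode %in% c("P2", "P4")
  classes <- sort(unique(dataset$species))
  rep_seeds <- plan$seeds

  rows <- list()
  reports <- list()
  for (r in seq_len(plan$n_repeats)) {
    split <- split_recordings(dataset, plan, rep_seeds[r])
    train_ids <- split$source_id[split$role == "train"]
    test_ids <- split$source_id[split$role == "test"]
    train_feats <- features[features$source_id %in% train_ids, ]
    test_feats <- features[features$source_id %in% test_ids, ]
    if (frame_mode) {
      train_feats <- balance_classes(train_feats, seed = rep_seeds[r], classes = classes)
    }
    cfg <- config
    cfg$seed <- rep_seeds[r]
    net <- train_network(train_feats, cfg)
    pred <- predict(net, test_feats)
    truth <- test_feats$species

    if (frame_mode) {
      reports[[paste0("frame_r", r)]] <- compute_metrics(
        confusion_matrix(truth, pred, classes))
      rows[[length(rows) + 1]] <- report_row(reports[[paste0("frame_r", r)]],
                                             r, "frame", NA_integer_)
      by_rec <- split(seq_len(nrow(test_feats)), test_feats$source_id)
      for (m in group_sizes) {
        gt <- character(0); gp <- character(0)
        for (idx in by_rec) {
          votes <- majority_vote(pred[idx], m)
          gp <- c(gp, votes)
          gt <- c(gt, rep(truth[idx][1], length(votes)))
        }
        rep_g <- compute_metrics(confusion_matrix(gt, gp, classes))
        reports[[sprintf("group%d_r%d", m, r)]] <- rep_g
        rows[[length(rows) + 1]] <- report_row(rep_g, r, "group", m)
      }
      vt <- vapply(by_rec, function(idx) truth[idx][1], character(1))
      vp <- vapply(by_rec, function(idx) vocalization_decision(pred[idx]), character(1))
      rep_v <- compute_metrics(confusion_matrix(vt, vp, classes))
      reports[[paste0("voc_r", r)]] <- rep_v
      rows[[length(rows) + 1]] <- report_row(rep_v, r, "vocalization", NA_integer_)
    } else {
      rep_v <- compute_metrics(confusion_matrix(truth, pred, classes))
      reports[[paste0("voc_r", r)]] <- rep_v
      rows[[length(rows) + 1]] <- report_row(rep_v, r, "vocalization", NA_integer_)
    }
  }
  repeats <- dplyr::bind_rows(rows)
  summary <- repeats |>
    dplyr::group_by(.data$granularity, .data$group_size) |>
    dplyr::summarise(dplyr::across(
      c("accuracy", "macro_precision", "macro_recall", "macro_f1"),
      list(mean = mean, sd = stats::sd)), n_repeats = dplyr::n(),
      .groups = "drop")
  structure(
    list(repeats = repeats, summary = summary, reports = reports,
         mode = mode, params = params, plan = plan),
    class = "protocol_report"
  )
}

report_row <- function(report, r, granularity, group_size) {
  tibble(`repeat` = r, granularity = granularity, group_size = group_size,
         n_tests = report$n_tests, accuracy = report$accuracy,
         macro_precision = report$macro_precision,
         macro_recall = report$macro_recall, macro_f1 = report$macro_f1)
}

#' @export
print.protocol_report <- function(x, ...) {
  cat(sprintf("<protocol_report> mode %s, %d repeats\n", x$mode, x$plan$n_repeats))
  print(x$summary)
  invisible(x)
}

#' @export
tidy.protocol_report <- function(x, ...) x$repeats

#' @export
glance.protocol_report <- function(x, ...) x$summary

#' Run the dual-network agreement/rejection protocol
#'
#' Trains two frame-mode networks on features extracted with two different
#' frame durations. Each test recording gets one decision per network (the
#' mode of its frame decisions); the test is accepted only when the two
#' decisions agree, and the recognition rate is computed over accepted tests
#' only. Single-network vocalization-level results on the same test sets are
#' reported for comparison.
#'
#' @inheritParams run_protocol
#' @param frame_ms_a,frame_ms_b frame durations (ms) of the two networks.
#' @param mode frame-granularity feature mode (`"P2"` or `"P4"`).
#' @return a `dual_report` with per-repeat rows for networks `A`, `B` and
#'   `dual` (accuracy, rejected counts) and the underlying reports.
#' @export
run_dual_protocol <- function(dataset, params = feature_params(),
                              frame_ms_a = 20, frame_ms_b = 80,
                              plan = split_plan(), config = mlp_config(),
                              mode = "P4") {
  stopifnot(mode %in% c("P2", "P4"))
  params_a <- params; params_a$frame_duration_ms <- frame_ms_a
  params_b <- params; params_b$frame_duration_ms <- frame_ms_b
  feats_a <- build_feature_table(dataset, mode = mode, params = params_a)
  feats_b <- build_feature_table(dataset, mode = mode, params = params_b)
  classes <- sort(unique(dataset$species))
  rows <- list()
  reports <- list()
  for (r in seq_len(plan$n_repeats)) {
    split <- split_recordings(dataset, plan, plan$seeds[r])
    test_ids <- split$source_id[split$role == "test"]
    decide <- function(features, offset) {
      train_f <- features[features$source_id %in%
                            split$source_id[split$role == "train"], ]
      test_f <- features[features$source_id %in% test_ids, ]
      train_f <- balance_classes(train_f, seed = plan$seeds[r] + offset,
                                 classes = classes)
      cfg <- config
      cfg$seed <- plan$seeds[r] + offset
      net <- train_network(train_f, cfg)
      pred <- predict(net, test_f)
      by_rec <- split(pred, test_f$source_id)
      tibble(source_id = names(by_rec),
             decision = vapply(by_rec, vocalization_decision, character(1)))
    }
    dec_a <- decide(feats_a, 0L)
    dec_b <- decide(feats_b, 1L)
    both <- dplyr::inner_join(dec_a, dec_b, by = "source_id",
                              suffix = c("_a", "_b")) |>
      dplyr::left_join(dplyr::distinct(dataset[, c("source_id", "species")]),
                       by = "source_id") |>
      dplyr::mutate(decision = dual_decision(.data$decision_a, .data$decision_b))
    accepted <- !is.na(both$decision)
    rep_a <- compute_metrics(confusion_matrix(both$species, both$decision_a, classes))
    rep_b <- compute_metrics(confusion_matrix(both$species, both$decision_b, classes))
    rows[[length(rows) + 1]] <- dplyr::bind_rows(
      dual_row(r, "A", frame_ms_a, rep_a, 0L),
      dual_row(r, "B", frame_ms_b, rep_b, 0L))
    if (any(accepted)) {
      rep_d <- compute_metrics(
        confusion_matrix(both$species[accepted], both$decision[accepted], classes),
        rejected = sum(!accepted))
      rows[[length(rows) + 1]] <- dual_row(r, "dual", NA_real_, rep_d, sum(!accepted))
      reports[[paste0("dual_r", r)]] <- rep_d
    } else {
      rlang::warn(sprintf("Repeat %d: every test rejected by the dual rule", r))
    }
    reports[[paste0("A_r", r)]] <- rep_a
    reports[[paste0("B_r", r)]] <- rep_b
  }
  repeats <- dplyr::bind_rows(rows)
  structure(
    list(repeats = repeats, reports = reports,
         frame_ms = c(A = frame_ms_a, B = frame_ms_b), plan = plan),
    class = "dual_report"
  )
}

dual_row <- function(r, network, frame_ms, report, rejected) {
  tibble(`repeat` = r, network = network, frame_ms = frame_ms,
         n_tests = report$n_tests, rejected = rejected,
         accuracy = report$accuracy, macro_f1 = report$macro_f1)
}

#' @export
print.dual_report <- function(x, ...) {
  cat(sprintf("<dual_report> frame durations %g/%g ms, %d repeats\n",
              x$frame_ms[1], x$frame_ms[2], x$plan$n_repeats))
  print(x$repeats)
  invisible(x)
}

#' @export
tidy.dual_report <- function(x, ...) x$repeats

#' Threshold sensitivity sweeps
#'
#' For each `ET` value, the mean percentage of frames kept by energy-based
#' silence removal across the dataset; for each `ftT` value, the mean
#' retained share of the analyzable frequency interval. Both are
#' non-increasing in their threshold by construction.
#'
#' @param dataset tibble with a `clip` list-column.
#' @param ET_grid energy-threshold fractions to sweep.
#' @param ftT_grid spectral-threshold fractions to sweep.
#' @param frame_duration_ms framing used for both sweeps.
#' @return list of two tibbles: `kept_frames` (`ET`, `kept_pct`) and
#'   `frequency_interval` (`ftT`, `retained_pct`).
#' @export
threshold_sensitivity <- function(dataset,
                                  ET_grid = c(0.0001, 0.0005, 0.001, 0.005, 0.01),
                                  ftT_grid = c(0.01, 0.05, 0.1, 0.5),
                                  frame_duration_ms = 40) {
  fseqs <- purrr::map(dataset$clip, frame_signal, frame_duration_ms = frame_duration_ms)
  fseqs <- purrr::keep(fseqs, ~ .x$Ns_i > 0)
  kept <- purrr::map_dfr(ET_grid, function(et) {
    fr <- purrr::map_dbl(fseqs, function(fs_) {
      e <- frame_time_energies(fs_)
      thr <- activity_threshold(e, et)
      mean(e > thr[["TE"]])
    })
    tibble(ET = et, kept_pct = 100 * mean(fr))
  })
  interval <- purrr::map_dfr(ftT_grid, function(ftt) {
    fr <- purrr::map_dbl(fseqs, interval_reduction, ftT = ftt)
    tibble(ftT = ftt, retained_pct = 100 * mean(fr))
  })
  list(kept_frames = kept, frequency_interval = interval)
}
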