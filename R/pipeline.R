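# End-to-end orchestration: simulate (or load) inputs, run both detection
# tracks, annotate TSDs, estimate frequencies, score against truth, and
# optionally persist every stage artifact plus a manifest.

#' Run the full TE-calling pipeline on a synthetic benchmark
#'
#' Chains [simulate_te_benchmark()], [call_insider()] on the truth contig
#' alignment, [call_outsider()] on the truth read alignments,
#' [annotate_tsd()], [estimate_frequencies()] and [benchmark_calls()].
#' With `out_dir` set, stage outputs (genomes, reads, alignments, call and
#' truth BEDs) and a JSON manifest (config snapshot, seed, per-stage counts)
#' are written there; a rerun with the same recipe and config reproduces the
#' outputs byte for byte.
#'
#' @param recipe A [simulation_recipe()] (use [scale_recipe()] for desk
#'   scale).
#' @param config A [te_config()].
#' @param out_dir Optional output directory.
#' @param tolerance Benchmark matching tolerance (bp).
#' @return A list of class `te_run`: the simulation, insider/outsider and
#'   combined annotated calls, the `te_benchmark` scores (combined plus
#'   per-track), and the manifest.
#' @export
run_te_pipeline <- function(recipe = scale_recipe(simulation_recipe(), 0.1),
                            config = te_config(), out_dir = NULL,
                            tolerance = 30) {
  config <- as_te_config(config)
  sim <- simulate_te_benchmark(recipe)
  insider <- call_insider(sim$reference, sim$assembly, sim$library,
                          sim$contig_alignment, config) |>
    annotate_tsd(sim$assembly, config = config)
  outsider <- call_outsider(sim$assembly, sim$reads, sim$library,
                            sim$alignments, config) |>
    annotate_tsd(sim$assembly, reads = sim$reads, config = config)
  insider <- estimate_frequencies(insider, sim$alignments, sim$library,
                                  config)
  outsider <- estimate_frequencies(outsider, sim$alignments, sim$library,
                                   config)
  combined <- bind_rows(
    insider |> select(dplyr::any_of(bed_call_columns), "cand_start",
                      "cand_end"),
    outsider |> select(dplyr::any_of(bed_call_columns), "cand_start",
                       "cand_end")
  ) |> arrange(.data$contig, .data$start)
  scores <- list(
    combined = benchmark_calls(combined, sim$truth, tolerance),
    insider = benchmark_calls(
      insider, sim$truth |> filter(.data$class_label == "INSIDER"),
      tolerance),
    outsider = benchmark_calls(
      outsider, sim$truth |> filter(.data$class_label == "OUTSIDER"),
      tolerance)
  )
  manifest <- list(
    package = as.character(utils::packageVersion("telltale")),
    seed = recipe$seed,
    recipe = unclass(recipe),
    config = unclass(config),
    tolerance = tolerance,
    stage_counts = list(
      reads = nrow(sim$reads),
      truth_insider = sum(sim$truth$class_label == "INSIDER"),
      truth_outsider = sum(sim$truth$class_label == "OUTSIDER"),
      insider_calls = nrow(insider),
      insider_deletions = sum(insider$kind == "deletion"),
      outsider_calls = nrow(outsider),
      combined_calls = nrow(combined)
    ),
    metrics = as.list(scores$combined$metrics)
  )
  run <- structure(list(
    sim = sim, insider = insider, outsider = outsider, combined = combined,
    scores = scores, manifest = manifest
  ), class = "te_run")
  if (!is.null(out_dir)) write_run(run, out_dir)
  run
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  sim <- run$sim
  Biostrings::writeXStringSet(sim$reference,
                              file.path(out_dir, "reference.fa"))
  Biostrings::writeXStringSet(sim$assembly, file.path(out_dir, "assembly.fa"))
  write_te_library(sim$library, file.path(out_dir, "te_library.fa"))
  write_reads(sim$reads, file.path(out_dir, "reads.fq"))
  write_alignments_sam(
    sim$alignments,
    setNames(Biostrings::width(sim$assembly), names(sim$assembly)),
    file.path(out_dir, "reads_vs_assembly.sam"))
  truth_bed <- sim$truth |>
    mutate(start = .data$position,
           end = if_else(.data$class_label == "INSIDER",
                         .data$position + .data$insert_size,
                         .data$position + 1))
  write_truth_bed(truth_bed, file.path(out_dir, "truth.bed"))
  write_calls_bed(run$insider, file.path(out_dir, "insider.bed"))
  write_calls_bed(run$outsider, file.path(out_dir, "outsider.bed"))
  write_calls_bed(run$combined, file.path(out_dir, "calls.bed"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.te_run <- function(x, ...) {
  sc <- x$manifest$stage_counts
  cat(sprintf(
    "TE pipeline run (seed %d): %d reads; truth %d insider + %d outsider\n",
    x$manifest$seed, sc$reads, sc$truth_insider, sc$truth_outsider))
  cat(sprintf("  calls: %d insider (%d deletions), %d outsider\n",
              sc$insider_calls, sc$insider_deletions, sc$outsider_calls))
  print(x$scores$combined)
  invisible(x)
}

#' @describeIn run_te_pipeline Combined annotated call table.
#' @param x A `te_run` object.
#' @param ... Unused.
#' @method tidy te_run
#' @export
tidy.te_run <- function(x, ...) {
  as_tibble(x$combined)
}

#' @describeIn run_te_pipeline One-row run summary (stage counts + combined
#'   metrics).
#' @method glance te_run
#' @export
glance.te_run <- function(x, ...) {
  bind_cols(as_tibble(x$manifest$stage_counts),
            x$scores$combined$metrics |>
              select("sensitivity", "fp_fraction"))
}
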