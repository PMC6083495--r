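#' Run the full DoG pipeline
#'
#' Executes the complete workflow on a dataset: build the most-inclusive
#' loci annotation, preprocess all samples (library-type inference, strand
#' normalization, downsampling to a common depth), discover DoGs per
#' sample, intersect replicates within each condition, merge the
#' per-condition sets into one unified annotation, and quantify every
#' sample's DoG expression (RPKM) over that unified annotation.
#'
#' The run configuration is serialized into the output directory together
#' with the package version, and every stage's output file is kept, so a
#' run is fully reproducible from its `manifest.json`.
#'
#' @param config a list (or YAML path) with elements:
#' \describe{
#'   \item{annotations}{character vector of GTF paths.}
#'   \item{samples}{list of `list(name=, path=, condition=)`; `path` is a
#'     SAM/BAM file.  In-memory read sets are accepted in place of paths.}
#'   \item{outdir}{output directory.}
#'   \item{params}{optional list passed to [dog_params()].}
#'   \item{target}{downsampling target, count or `"auto"` (default).}
#'   \item{seed}{base RNG seed (default 1).}
#'   \item{strand_threshold, strand_sample_size}{library-inference knobs.}
#'   \item{combine}{end-combination rule for replicate intersection,
#'     `"max"` (default) or `"min"`.}
#' }
#' @return invisibly, a list with the loci, manifest, per-sample DoG sets,
#'   per-condition common sets, the union annotation, the expression
#'   tables, and all file paths.
#' @export
run_all <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  for (field in c("annotations", "samples", "outdir"))
    if (is.null(config[[field]]))
      stop("config error: missing '", field, "'")
  for (ann in config$annotations)
    if (is.character(ann) && !file.exists(ann))
      stop("config error: annotation file not found: ", ann)
  for (s in config$samples) {
    if (is.null(s$name) || is.null(s$path))
      stop("config error: each sample needs 'name' and 'path'")
    if (is.character(s$path) && !file.exists(s$path))
      stop("config error: sample file not found: ", s$path)
  }
  params <- do.call(dog_params, as.list(config$params))
  target <- if (is.null(config$target)) "auto" else config$target
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  combine <- if (is.null(config$combine)) "max" else config$combine
  outdir <- config$outdir
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }

  loci <- stage("build-loci", build_loci(config$annotations))
  loci_path <- file.path(outdir, "loci.bed")
  write_bed(loci, loci_path)

  sample_names <- vapply(config$samples, `[[`, character(1), "name")
  conditions <- vapply(config$samples, function(s)
    if (is.null(s$condition)) "all" else s$condition, character(1))
  reads_in <- stats::setNames(
    lapply(config$samples, `[[`, "path"), sample_names)
  manifest <- stage("preprocess", preprocess_samples(
    reads_in, loci, target = target, seed = seed,
    sample_size = if (is.null(config$strand_sample_size)) 200000
                  else config$strand_sample_size,
    threshold = if (is.null(config$strand_threshold)) 0.8
                else config$strand_threshold))

  chrom_len <- GenomeInfoDb::seqlengths(manifest[[1]]$ds)
  dog_sets <- list(); dog_paths <- character(0)
  for (nm in sample_names) {
    dogs <- stage(paste0("get-dogs:", nm), discover_dogs(
      manifest[[nm]]$ds, loci, params, spec = manifest[[nm]]$spec,
      chrom_len = chrom_len))
    dog_sets[[nm]] <- dogs
    p <- file.path(outdir, paste0(nm, ".dogs.bed"))
    write_bed(dogs, p)
    dog_paths[nm] <- p
  }

  common_sets <- list(); common_paths <- character(0)
  per_condition <- list()
  for (cond in unique(conditions)) {
    members <- sample_names[conditions == cond]
    if (length(members) >= 2) {
      cc <- stage(paste0("common:", cond),
                  common_dogs(dog_sets[members], combine = combine))
      common_sets[[cond]] <- cc
      p <- file.path(outdir, paste0(cond, ".common.bed"))
      write_bed(cc, p)
      common_paths[cond] <- p
      per_condition[[cond]] <- cc
    } else {
      per_condition[[cond]] <- dog_sets[[members]]
    }
  }

  union_set <- stage("union", union_dogs(per_condition))
  union_path <- file.path(outdir, "union.bed")
  write_bed(union_set, union_path)

  expr_tables <- list(); expr_paths <- character(0)
  for (nm in sample_names) {
    ex <- stage(paste0("rpkm:", nm), compute_rpkm(
      manifest[[nm]]$ds, union_set, spec = manifest[[nm]]$spec))
    expr_tables[[nm]] <- ex
    p <- file.path(outdir, paste0(nm, ".dogs.tsv"))
    write_expression_table(ex, p)
    expr_paths[nm] <- p
  }

  run_info <- list(
    tool = "dogscan",
    version = as.character(utils::packageVersion("dogscan")),
    params = unclass(params),
    target = manifest[[1]]$target,
    seed = seed,
    combine = combine,
    samples = lapply(sample_names, function(nm) list(
      name = nm,
      condition = conditions[match(nm, sample_names)],
      total_mapped = manifest[[nm]]$total_mapped,
      downsample_seed = manifest[[nm]]$seed,
      layout = manifest[[nm]]$spec$layout,
      strandedness = manifest[[nm]]$spec$strandedness,
      concordance = manifest[[nm]]$spec$concordance_fraction,
      n_dogs = length(dog_sets[[nm]]))))
  jsonlite::write_json(run_info, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  invisible(list(loci = loci, manifest = manifest, dogs = dog_sets,
                 common = common_sets, union = union_set,
                 expression = expr_tables,
                 paths = list(loci = loci_path, dogs = dog_paths,
                              common = common_paths, union = union_path,
                              expression = expr_paths,
                              manifest = file.path(outdir,
                                                   "manifest.json"))))
}
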