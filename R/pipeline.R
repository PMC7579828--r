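#' Default pipeline configuration
#'
#' Returns the configuration skeleton understood by [run_pipeline()],
#' with every threshold of the evaluation surfaced as a named key:
#' genotype call-rate minimum 0.85, Mendelian-error maximum 0.02,
#' G/A22 blending weight 0.05, 25% phenotype masking over 10 LR
#' iterations, a 50 kb gene-search window and the 0.40 heritability
#' constraint of the association scan.
#'
#' @param seed top-level seed; per-stage seeds derive from it.
#' @param out_dir output directory.
#' @return A nested list; override entries and pass to [run_pipeline()].
#' @export
pipeline_config <- function(seed = 1L, out_dir = tempfile("hairshed_run")) {
  list(seed = seed,
       out_dir = out_dir,
       stages = c("simulate", "prep", "relmat", "fit", "validate", "gwas"),
       sim = list(),
       qc = list(call_rate_min = 0.85, mendel_max = 0.02),
       relmat = list(blend_weight = 0.05),
       fit = list(start = c(0.3, 0.1, 0.6), tol = 1e-6),
       validate = list(n_iter = 10L, fraction = 0.25),
       gwas = list(h2_fixed = 0.40, fdr = 0.05, window = 50000L,
                   min_reliability = 0.05))
}

#' Run the evaluation pipeline end-to-end
#'
#' Orchestrates simulate -> prep -> relmat -> fit -> validate -> gwas on
#' synthetic data, writing every stage's outputs as plain-text tables
#' under `out_dir` together with a JSON manifest recording seeds, file
#' hashes and per-stage summaries. Disabled stages are skipped; a stage
#' whose inputs were produced neither by an enabled upstream stage nor by
#' a previous run stops with an error naming the missing stage.
#'
#' @param config a [pipeline_config()] list, or the path of a YAML file
#'   holding one.
#' @return The manifest (invisibly written to `manifest.json`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(cfg$out_dir, f)
  on <- function(stage) stage %in% cfg$stages
  manifest <- list(seed = cfg$seed, stages = cfg$stages, summary = list())
  env <- new.env()

  if (on("simulate")) {
    sim_args <- utils::modifyList(list(seed = cfg$seed), cfg$sim)
    scfg <- do.call(sim_config, sim_args)
    env$ped <- simulate_pedigree(scfg)
    phen <- simulate_phenotypes(env$ped, scfg)
    env$records <- phen$records
    env$truth <- phen$truth
    gen <- simulate_genotypes(env$ped, scfg)
    set.seed(derive_seed(cfg$seed, "genotyped_subset"))
    n_geno <- round(nrow(env$ped) * scfg$genotyped_fraction)
    env$genotyped <- sort(sample(env$ped$animal, n_geno))
    env$geno <- gen$geno[env$genotyped, , drop = FALSE]
    env$map <- gen$map
    write_pedigree(env$ped, p("pedigree.csv"))
    utils::write.csv(env$records, p("records.csv"), row.names = FALSE)
    write_plink_raw(env$geno, p("genotypes.raw"))
    write_truth_tsv(env$truth$true_bv, p("truth.tsv"))
    manifest$summary$simulate <- list(n_animals = nrow(env$ped),
                                      n_records = nrow(env$records),
                                      n_genotyped = length(env$genotyped))
  }

  need <- function(obj, file, reader, stage) {
    if (!is.null(env[[obj]])) return(env[[obj]])
    if (file.exists(p(file))) {
      env[[obj]] <- reader(p(file))
      return(env[[obj]])
    }
    stop("stage input '", file, "' missing: enable stage '", stage,
         "' or provide the file", call. = FALSE)
  }

  if (on("prep")) {
    rec <- need("records", "records.csv", function(f)
      utils::read.csv(f, stringsAsFactors = FALSE), "simulate")
    ped <- need("ped", "pedigree.csv", read_pedigree, "simulate")
    meta <- data.frame(animal = ped$animal, sex = ped$sex,
                       birth_date = ped$birth_date)
    prep <- prep_records(rec, meta)
    env$prepared <- prep$records
    utils::write.csv(prep$records, p("prepared.csv"), row.names = FALSE)
    utils::write.table(prep$removal_log, p("removals.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$summary$prep <- list(n_kept = nrow(prep$records),
                                  n_removed = nrow(prep$removal_log),
                                  n_groups = nrow(prep$groups))
  }

  if (on("relmat")) {
    ped <- need("ped", "pedigree.csv", read_pedigree, "simulate")
    geno <- if (!is.null(env$geno)) env$geno else
      need("geno", "genotypes.raw", function(f)
        read_genotypes(f, "plink_raw")$geno, "simulate")
    qc <- genotype_qc(geno, ped, cfg$qc$call_rate_min, cfg$qc$mendel_max)
    gids <- rownames(qc$geno)
    ainv <- a_inverse(qc$ped)
    a22 <- a_matrix(qc$ped, ids = gids)
    G <- vanraden_g(qc$geno)
    Gw <- blend_g(G, a22, cfg$relmat$blend_weight)
    env$hinv <- h_inverse(ainv, solve(a22), solve(Gw), gids)
    env$grm <- Gw
    write_rel_tsv(env$hinv, p("h_inverse.tsv"))
    manifest$summary$relmat <- list(n_genotyped = length(gids),
                                    n_snps = ncol(qc$geno),
                                    dropped_snps = nrow(qc$report$dropped_snps))
  }

  if (on("fit")) {
    recs <- need("prepared", "prepared.csv", function(f)
      utils::read.csv(f, stringsAsFactors = FALSE), "prep")
    if (is.null(env$hinv)) stop("stage 'fit' needs stage 'relmat'",
                                call. = FALSE)
    fit <- fit_univariate(recs, env$hinv, start = cfg$fit$start,
                          tol = cfg$fit$tol)
    env$fit <- fit
    utils::write.table(fit$ebv, p("ebv.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    utils::write.table(data.frame(component = names(fit$varcomp),
                                  estimate = unname(fit$varcomp)),
                       p("varcomp.tsv"), sep = "\t", row.names = FALSE,
                       quote = FALSE)
    manifest$summary$fit <- list(varcomp = as.list(fit$varcomp),
                                 h2 = fit$params$h2,
                                 repeatability = fit$params$repeatability)
  }

  if (on("validate")) {
    recs <- need("prepared", "prepared.csv", function(f)
      utils::read.csv(f, stringsAsFactors = FALSE), "prep")
    if (is.null(env$hinv)) stop("stage 'validate' needs stage 'relmat'",
                                call. = FALSE)
    vc <- if (!is.null(env$fit)) unname(env$fit$varcomp) else NULL
    lr <- run_lr_validation(recs, env$hinv,
                            n_iter = cfg$validate$n_iter,
                            fraction = cfg$validate$fraction,
                            seed = derive_seed(cfg$seed, "lr"),
                            varcomp = vc)
    utils::write.table(lr$per_iteration, p("lr_iterations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(lr$summary, p("lr_summary.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$summary$validate <-
      as.list(setNames(lr$summary$mean, lr$summary$stat))
  }

  if (on("gwas")) {
    if (is.null(env$fit)) stop("stage 'gwas' needs stage 'fit'",
                               call. = FALSE)
    geno <- if (!is.null(env$geno)) env$geno else
      need("geno", "genotypes.raw", function(f)
        read_genotypes(f, "plink_raw")$geno, "simulate")
    dr <- deregress(env$fit$ebv, env$fit$varcomp[["var_a"]],
                    cfg$gwas$min_reliability)
    scan <- single_snp_scan(dr, geno, map = env$map,
                            h2_fixed = cfg$gwas$h2_fixed)
    utils::write.table(scan, p("gwas.tsv"), sep = "\t",
                       row.names = FALSE, quote = FALSE)
    manifest$summary$gwas <- list(n_snps = nrow(scan),
                                  n_hits = sum(scan$q < cfg$gwas$fdr))
  }

  files <- list.files(cfg$out_dir, full.names = TRUE)
  files <- files[!basename(files) %in% "manifest.json"]
  manifest$hashes <- as.list(tools::md5sum(files))
  names(manifest$hashes) <- basename(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}

# persist a relationship matrix as indexed upper-triangle TSV
write_rel_tsv <- function(m, path) {
  mm <- methods::as(methods::as(m, "CsparseMatrix"), "TsparseMatrix")
  ids <- rownames(m)
  keep <- mm@i <= mm@j
  df <- data.frame(row = ids[mm@i[keep] + 1L], col = ids[mm@j[keep] + 1L],
                   value = mm@x[keep])
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
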