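## ---- generic tab-delimited tables -----------------------------------------

fmt_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.10g", x))
}

#' Write / read a tab-delimited table
#'
#' All tabular artifacts (phenotypes, covariates, summary statistics, scores,
#' association results) use headered, UTF-8, tab-delimited files with numeric
#' columns formatted to 10 significant digits, making round-trips exact at
#' that precision. Reading is header-keyed: column order does not matter, but
#' a missing required column or a duplicated id is an error.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `write_tsv` invisibly returns `path`; `read_tsv` returns a data
#'   frame.
#' @export
write_tsv <- function(df, path) {
  out <- df
  for (j in seq_along(out)) {
    if (is.double(out[[j]])) out[[j]] <- fmt_num(out[[j]])
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_tsv
#' @param required Character vector of column names that must be present.
#' @param id_col Optional column checked for duplicates.
#' @export
read_tsv <- function(path, required = NULL, id_col = NULL) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    stop(sprintf("missing required column(s) in %s: %s", path,
                 paste(miss, collapse = ", ")))
  }
  if (!is.null(id_col) && anyDuplicated(df[[id_col]])) {
    stop(sprintf("duplicate %s in %s", id_col, path))
  }
  df
}

#' Tabular writers/readers for the standard artifacts
#'
#' Thin wrappers around [write_tsv()]/[read_tsv()] fixing the documented
#' column layouts: phenotypes `(individual_id, y, u, e, c)`, summary
#' statistics `(site_id, beta_hat, se, p, model_tag)`, covariates
#' `(individual_id, value)`, scores `(individual_id, z)`, test vectors
#' `(individual_id, raw_value)` and association results
#' `(replicate, model_tag, q_hat, q_true)`.
#'
#' @param pheno,effects,axis,scores,results The objects to serialize.
#' @param ids Individual identifiers (default `ind_1 ... ind_M`).
#' @param path File path.
#' @return Writers invisibly return `path`; readers return the parsed object.
#' @name artifact_tables
NULL

#' @rdname artifact_tables
#' @export
write_phenotype_table <- function(pheno, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_along(pheno$y))
  write_tsv(data.frame(individual_id = ids, y = pheno$y, u = pheno$u,
                       e = pheno$e, c = pheno$c), path)
}

#' @rdname artifact_tables
#' @export
read_phenotype_table <- function(path) {
  read_tsv(path, required = c("individual_id", "y", "u", "e", "c"),
           id_col = "individual_id")
}

#' @rdname artifact_tables
#' @export
write_summary_stats <- function(effects, path) {
  write_tsv(data.frame(site_id = effects$site_id, beta_hat = effects$beta_hat,
                       se = effects$se, p = effects$p,
                       model_tag = attr(effects, "model_tag") %||% "none"),
            path)
}

#' @rdname artifact_tables
#' @export
read_summary_stats <- function(path) {
  df <- read_tsv(path, required = c("site_id", "beta_hat", "se", "p"),
                 id_col = "site_id")
  out <- df[, c("site_id", "beta_hat", "se", "p")]
  attr(out, "model_tag") <- if ("model_tag" %in% names(df)) df$model_tag[1] else "none"
  class(out) <- c("effect_estimates", "data.frame")
  out
}

#' @rdname artifact_tables
#' @export
write_axis_table <- function(axis, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_along(axis$values))
  write_tsv(data.frame(individual_id = ids, value = axis$values), path)
}

#' @rdname artifact_tables
#' @export
write_scores_table <- function(scores, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_along(scores$z))
  write_tsv(data.frame(individual_id = ids, z = scores$z), path)
}

#' @rdname artifact_tables
#' @export
read_test_vector_table <- function(path, kind = "custom") {
  df <- read_tsv(path, required = c("individual_id", "raw_value"),
                 id_col = "individual_id")
  standardize_test_vector(df$raw_value, kind = kind)
}

#' @rdname artifact_tables
#' @export
write_results_table <- function(results, path) {
  df <- do.call(rbind, lapply(results, function(r) {
    data.frame(replicate = r$replicate, model_tag = r$model_tag,
               q_hat = r$q_hat, q_true = r$q_true)
  }))
  write_tsv(df, path)
}

## ---- dosage tables ---------------------------------------------------------

#' Write / read a genotype panel as a dosage table
#'
#' Tab-delimited individuals x sites layout: first two columns
#' `individual_id` and `label`, then one integer column per site headed by
#' its site id. Grid deme coordinates are encoded in labels of the form
#' `deme_<row>_<col>` and recovered on read. Round-trips are exact.
#'
#' @param panel A `genotype_panel`.
#' @param path File path.
#' @param ids Individual identifiers (default `ind_1 ...`).
#' @return `read_dosage_table` returns a `genotype_panel`.
#' @export
write_dosage_table <- function(panel, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_len(n_individuals(panel)))
  df <- data.frame(individual_id = ids, label = panel$labels,
                   panel$dosages, check.names = FALSE)
  names(df)[-(1:2)] <- panel$site_ids
  write_tsv(df, path)
}

#' @rdname write_dosage_table
#' @export
read_dosage_table <- function(path) {
  df <- read_tsv(path, required = c("individual_id", "label"),
                 id_col = "individual_id")
  dos <- as.matrix(df[, -(1:2), drop = FALSE])
  coords <- NULL
  cm <- regmatches(df$label, regexec("^deme_([0-9]+)_([0-9]+)$", df$label))
  if (all(lengths(cm) == 3)) {
    coords <- cbind(row = as.integer(vapply(cm, `[`, "", 2)),
                    col = as.integer(vapply(cm, `[`, "", 3)))
  }
  genotype_panel(dos, df$label, site_ids = colnames(dos), coords = coords)
}

## ---- VCF -------------------------------------------------------------------

#' Write / read a genotype panel as VCF
#'
#' Writes VCF 4.2 with one biallelic record per site and unphased diploid GT
#' fields; individual labels travel in a sidecar sample table
#' (`<path>.samples`, columns `individual_id`, `label`). Reading uses vcfR
#' and refuses multi-allelic records or missing genotypes with an error
#' naming the offending record and sample, since downstream estimators assume
#' complete dosages.
#'
#' @param panel A `genotype_panel`.
#' @param path Path to the `.vcf` file.
#' @param ids Sample names (default `ind_1 ...`).
#' @return `read_vcf` returns a `genotype_panel`.
#' @export
write_vcf <- function(panel, path, ids = NULL) {
  ids <- ids %||% paste0("ind_", seq_len(n_individuals(panel)))
  gt_code <- c("0/0", "0/1", "1/1")
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##source=strataxis",
               '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", ids), collapse = "\t")), con)
  L <- n_sites(panel)
  gt <- matrix(gt_code[panel$dosages + 1L], nrow = n_individuals(panel))
  lines <- vapply(seq_len(L), function(l) {
    paste(c("1", l, panel$site_ids[l], "A", "T", ".", "PASS", ".", "GT",
            gt[, l]), collapse = "\t")
  }, "")
  writeLines(lines, con)
  write_tsv(data.frame(individual_id = ids, label = panel$labels),
            paste0(path, ".samples"))
  invisible(path)
}

#' @rdname write_vcf
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  alt <- vcfR::getALT(v)
  multi <- grepl(",", alt)
  if (any(multi)) {
    stop(sprintf("multi-allelic record(s) not supported: %s",
                 paste(utils::head(vcfR::getID(v)[multi], 5), collapse = ", ")))
  }
  gt <- vcfR::extract.gt(v, element = "GT")
  miss <- is.na(gt) | gt %in% c(".", "./.", ".|.")
  if (any(miss)) {
    w <- which(miss, arr.ind = TRUE)[1, ]
    stop(sprintf("missing genotype at record %s, sample %s",
                 rownames(gt)[w[1]], colnames(gt)[w[2]]))
  }
  dos <- matrix(vapply(strsplit(gt, "[/|]"),
                       function(al) sum(al == "1"), 0L),
                nrow = nrow(gt))
  if (!all(dos %in% 0:2 & matrix(vapply(strsplit(gt, "[/|]"), length, 0L),
                                 nrow = nrow(gt)) == 2L)) {
    stop("genotypes must be diploid biallelic (alleles 0/1)")
  }
  sample_path <- paste0(path, ".samples")
  labels <- if (file.exists(sample_path)) {
    st <- read_tsv(sample_path, required = c("individual_id", "label"),
                   id_col = "individual_id")
    st$label[match(colnames(gt), st$individual_id)]
  } else {
    rep("sample", ncol(gt))
  }
  genotype_panel(t(dos), labels, site_ids = rownames(gt))
}

## ---- configs and manifests -------------------------------------------------

#' Write / read a demography configuration
#'
#' Structured YAML with keys `kind` (`tree` or `grid`) and the demography
#' parameters, plus optional simulation keys `maf`, `L`, `seed`,
#' `n_per_pop`.
#'
#' @param model A `tree_demography` or `grid_demography`.
#' @param path File path.
#' @param extra Named list of extra simulation keys to store.
#' @return `read_demography_config` returns a list with `$model` and any
#'   extra keys.
#' @export
write_demography_config <- function(model, path, extra = list()) {
  cfg <- if (inherits(model, "tree_demography")) {
    list(kind = "tree", ne = model$ne,
         splits = c(model$t_deep, model$t_shallow), topology = model$topology)
  } else {
    list(kind = "grid", rows = model$rows, cols = model$cols,
         m = model$migration_rate, deme_size = model$deme_size,
         samples_per_deme = model$samples_per_deme)
  }
  yaml::write_yaml(c(cfg, extra), path)
  invisible(path)
}

#' @rdname write_demography_config
#' @export
read_demography_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  model <- switch(cfg$kind,
    tree = tree_demography(ne = cfg$ne, t_deep = cfg$splits[1],
                           t_shallow = cfg$splits[2],
                           topology = cfg$topology %||% "confounded"),
    grid = grid_demography(rows = cfg$rows, cols = cfg$cols,
                           migration_rate = cfg$m, deme_size = cfg$deme_size,
                           samples_per_deme = cfg$samples_per_deme),
    stop(sprintf("unknown demography kind '%s'", cfg$kind)))
  c(list(model = model), cfg[setdiff(names(cfg), c("kind", "ne", "splits",
                                                   "topology", "rows", "cols",
                                                   "m", "deme_size",
                                                   "samples_per_deme"))])
}

#' Write a run manifest
#'
#' Machine-readable YAML echoing the configuration, seed registry, stage
#' timings and artifact paths of an experiment run. Every referenced artifact
#' path must exist at write time.
#'
#' @param path Output path.
#' @param config List echoing the run configuration.
#' @param seeds Named list/vector of seeds used.
#' @param stages Optional named vector of per-stage timings (seconds).
#' @param artifacts Character vector of paths produced by the run.
#' @export
write_manifest <- function(path, config, seeds, stages = NULL,
                           artifacts = character()) {
  missing <- artifacts[!file.exists(artifacts)]
  if (length(missing)) {
    stop(sprintf("manifest references missing artifact(s): %s",
                 paste(missing, collapse = ", ")))
  }
  yaml::write_yaml(list(package = "strataxis",
                        version = as.character(utils::packageVersion("strataxis")),
                        config = config, seeds = as.list(seeds),
                        stages = as.list(stages),
                        artifacts = as.list(artifacts)), path)
  invisible(path)
}
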