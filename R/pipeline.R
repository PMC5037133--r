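fmt_num <- function(x) {
  out <- formatC(x, digits = 17, format = "g")
  out[is.na(x)] <- ""
  out
}

#' Write a labeled numeric matrix as TSV
#'
#' First column holds the row ids; numbers are serialized at full double
#' precision; missing values become empty cells.
#'
#' @param m numeric matrix with rownames.
#' @param path output file.
#' @param id_col name for the id column (default `"sample_id"`).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, id_col = "sample_id") {
  m <- as.matrix(m)
  if (is.null(rownames(m))) stop_bad("matrix must have rownames")
  body <- apply(m, 2, fmt_num)
  if (!is.matrix(body)) body <- matrix(body, nrow = nrow(m))
  lines <- c(paste(c(id_col, colnames(m)), collapse = "\t"),
             paste(rownames(m),
                   apply(body, 1, paste, collapse = "\t"), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labeled numeric matrix from TSV
#'
#' Inverse of [write_matrix_tsv()]. Ragged rows, duplicate ids and
#' non-numeric cells are errors that name the offending line or cell;
#' empty cells and `"NA"` read as missing.
#'
#' @param path TSV file with an id column first.
#' @return Numeric matrix with rownames.
#' @export
read_matrix_tsv <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 2L) stop_bad(path, ": no data rows")
  # sentinel keeps trailing empty fields countable
  cells <- strsplit(paste0(lines, "\tEOL"), "\t", fixed = TRUE)
  cells <- lapply(cells, function(v) v[-length(v)])
  lens <- lengths(cells)
  width <- lens[1]
  if (any(lens != width))
    stop_bad(path, ": ragged row at line ", which(lens != width)[1])
  header <- cells[[1]]
  ids <- vapply(cells[-1], `[[`, "", 1)
  if (anyDuplicated(ids))
    stop_bad(path, ": duplicate id '", ids[duplicated(ids)][1], "'")
  m <- matrix(NA_real_, length(ids), width - 1L,
              dimnames = list(ids, header[-1]))
  for (i in seq_along(ids)) {
    v <- cells[[i + 1L]][-1]
    blank <- v == "" | v == "NA"
    num <- suppressWarnings(as.numeric(v))
    bad <- which(is.na(num) & !blank)
    if (length(bad))
      stop_bad(path, ": non-numeric cell '", v[bad[1]], "' at row '",
               ids[i], "', column '", header[bad[1] + 1L], "'")
    m[i, ] <- num
  }
  m
}

#' Write / read an OTU table (counts + metadata TSVs)
#'
#' @param x an [otu_table].
#' @param counts_path,metadata_path output files.
#' @return Paths, invisibly.
#' @export
write_otu_tsv <- function(x, counts_path, metadata_path) {
  stopifnot(inherits(x, "otu_table"))
  write_matrix_tsv(x$counts, counts_path)
  meta <- cbind(sample_id = rownames(x$metadata),
                x$metadata[c("site", "month", "fraction")])
  write.table(meta, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(counts_path, metadata_path))
}

#' @rdname write_otu_tsv
#' @export
read_otu_tsv <- function(counts_path, metadata_path) {
  counts <- read_matrix_tsv(counts_path)
  meta <- utils::read.delim(metadata_path, sep = "\t",
                            stringsAsFactors = FALSE)
  rownames(meta) <- meta$sample_id
  otu_table(counts, meta)
}

#' Write EcoPlate series in long format
#'
#' One row per (plate, timepoint, well); the layout travels separately
#' via [default_ecoplate_layout()]-shaped TSVs.
#'
#' @param plates named list of [ecoplate_series].
#' @param path output TSV.
#' @return `path`, invisibly.
#' @export
write_ecoplate_tsv <- function(plates, path) {
  rows <- lapply(plates, function(p) {
    data.frame(sample_id = p$sample_id,
               timepoint = rep(p$timepoints, each = nrow(p$absorbance)),
               well = rep(rownames(p$absorbance), length(p$timepoints)),
               absorbance = fmt_num(as.vector(p$absorbance)))
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' @rdname write_ecoplate_tsv
#' @param layout plate layout for reconstruction.
#' @export
read_ecoplate_tsv <- function(path, layout = default_ecoplate_layout()) {
  d <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  lapply(split(d, d$sample_id), function(dd) {
    tps <- sort(unique(dd$timepoint))
    ab <- matrix(NA_real_, nrow(layout), length(tps),
                 dimnames = list(layout$well, NULL))
    ab[cbind(match(dd$well, rownames(ab)),
             match(dd$timepoint, tps))] <- dd$absorbance
    ecoplate_series(ab, tps, layout, sample_id = dd$sample_id[1])
  })
}

#' Write a synthetic dataset to the pipeline's TSV formats
#'
#' @param ds a [simulate_dataset()] result.
#' @param dir output directory (created if needed).
#' @return Character vector of files written.
#' @export
write_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "synthetic_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- character(0)
  p <- function(...) file.path(dir, paste0(...))
  for (s in names(ds$sites)) {
    si <- ds$sites[[s]]
    write_otu_tsv(si$otu_rdna, p(s, "_rdna_counts.tsv"), p(s, "_rdna_metadata.tsv"))
    write_otu_tsv(si$otu_rrna, p(s, "_rrna_counts.tsv"), p(s, "_rrna_metadata.tsv"))
    write_matrix_tsv(si$env, p(s, "_env.tsv"), id_col = "month")
    fn <- do.call(cbind, lapply(si$functions, function(d) d$value))
    rownames(fn) <- si$functions[[1]]$month
    write_matrix_tsv(fn, p(s, "_functions.tsv"), id_col = "month")
    write_ecoplate_tsv(si$aux$ecoplates, p(s, "_ecoplates.tsv"))
    for (nm in c("doc", "o2", "growth", "cdom")) {
      d <- si$aux[[nm]]
      d[] <- lapply(d, function(col) if (is.numeric(col)) fmt_num(col) else col)
      write.table(d, p(s, "_", nm, ".tsv"), sep = "\t", quote = FALSE,
                  row.names = FALSE)
    }
    files <- c(files, p(s, c("_rdna_counts.tsv", "_rdna_metadata.tsv",
                             "_rrna_counts.tsv", "_rrna_metadata.tsv",
                             "_env.tsv", "_functions.tsv", "_ecoplates.tsv",
                             "_doc.tsv", "_o2.tsv", "_growth.tsv",
                             "_cdom.tsv")))
  }
  write.table(ds$truth, file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  c(files, file.path(dir, "truth.tsv"))
}

validate_run_config <- function(config) {
  errs <- character(0)
  need <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  need(!is.null(config$out_dir), "missing field: out_dir")
  need(is.numeric(config$seed %||% NULL) || is.null(config$inputs),
       "missing field: seed")
  need(is.numeric(config$seed %||% NA), "missing field: seed")
  has_sim <- !is.null(config$simulate)
  has_in <- !is.null(config$inputs)
  need(xor(has_sim, has_in),
       "exactly one of `simulate` or `inputs` must be given")
  if (has_in) {
    req <- c("rdna_counts", "rdna_metadata", "rrna_counts", "rrna_metadata",
             "env", "functions")
    for (s in names(config$inputs)) {
      for (f in req) {
        path <- config$inputs[[s]][[f]]
        if (is.null(path)) {
          errs <- c(errs, sprintf("missing field: inputs$%s$%s", s, f))
        } else if (!file.exists(path)) {
          errs <- c(errs, sprintf("file not found: inputs$%s$%s = %s", s, f, path))
        }
      }
    }
  }
  if (length(errs))
    stop_bad("invalid run config:\n  ", paste(errs, collapse = "\n  "))
  invisible(TRUE)
}

load_site_inputs <- function(paths) {
  env <- read_matrix_tsv(paths$env)
  fn <- read_matrix_tsv(paths$functions)
  fns <- lapply(seq_len(ncol(fn)), function(j)
    data.frame(month = as.integer(rownames(fn)), value = fn[, j]))
  names(fns) <- colnames(fn)
  aux <- list()
  if (!is.null(paths$ecoplates))
    aux$ecoplates <- read_ecoplate_tsv(paths$ecoplates)
  for (nm in c("doc", "o2", "growth", "cdom"))
    if (!is.null(paths[[nm]]))
      aux[[nm]] <- utils::read.delim(paths[[nm]], sep = "\t")
  list(otu_rdna = read_otu_tsv(paths$rdna_counts, paths$rdna_metadata),
       otu_rrna = read_otu_tsv(paths$rrna_counts, paths$rrna_metadata),
       env = env, functions = fns, aux = aux)
}

#' Run the full analysis pipeline
#'
#' Executes, in order: data generation or loading; OTU filtering,
#' rarefaction, relative abundance, Bray-Curtis dissimilarity and
#' hierarchical clustering; EcoPlate normalization, presence scoring and
#' substrate-profile distances; Mantel and PERMANOVA stages; rate
#' derivations (DOC decay fit, respiration, BGE, thymidine cells, CDOM
#' slope); and two-site lasso driver inference with cross-site consensus.
#' Every stage writes TSV results under `out_dir` and is checksummed into
#' a JSON run manifest; identical config and seed reproduce identical
#' checksums.
#'
#' @param config a list or YAML file path. Fields: `out_dir`; `seed`;
#'   either `simulate` (arguments for [sim_config()]) or `inputs` (per
#'   site: paths `rdna_counts`, `rdna_metadata`, `rrna_counts`,
#'   `rrna_metadata`, `env`, `functions`, optional `ecoplates`, `doc`,
#'   `o2`, `growth`, `cdom`); optional `rarefaction_depth` (16000),
#'   `lasso` (`k_folds`, `rule`, `n_lambda`), `mantel_permutations`
#'   (9999), `permanova_permutations` (999).
#' @return The run manifest (also written to `out_dir/manifest.json`),
#'   invisibly.
#' @export
run_pipeline <- function(config) {
  if (is.character(config) && length(config) == 1L)
    config <- yaml::read_yaml(config)
  validate_run_config(config)
  out <- config$out_dir
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed)
  depth <- config$rarefaction_depth %||% 16000
  manifest <- list(package = "codriver",
                   version = as.character(packageVersion("codriver")),
                   seed = seed,
                   config = config[setdiff(names(config), "out_dir")],
                   stages = list())
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    files <- tryCatch(expr, error = function(e)
      stop_bad("stage '", name, "' failed: ", conditionMessage(e)))
    sums <- md5sum(files)
    names(sums) <- basename(names(sums))
    manifest$stages[[name]] <<- list(
      outputs = as.list(sums),
      elapsed = round(proc.time()[["elapsed"]] - t0, 3))
    invisible(files)
  }

  # stage: data --------------------------------------------------------
  ds <- NULL
  stage("data", {
    if (!is.null(config$simulate)) {
      simargs <- config$simulate
      simargs$seed <- simargs$seed %||% seed
      ds <- simulate_dataset(do.call(sim_config, simargs))
      write_dataset(ds, file.path(out, "data"))
    } else {
      ds <- list(sites = lapply(config$inputs, load_site_inputs),
                  truth = NULL, config = NULL)
      character(0)
    }
  })

  # stage: otu ---------------------------------------------------------
  odir <- file.path(out, "otu"); dir.create(odir, showWarnings = FALSE)
  filtered <- list(); rarefied <- list()
  stage("otu", {
    files <- character(0)
    for (s in names(ds$sites)) {
      si <- ds$sites[[s]]
      fl <- list(rdna = filter_otus(si$otu_rdna),
                 rrna = filter_otus(si$otu_rrna))
      rr <- list(rdna = rarefy(fl$rdna, depth, seed = sub_seed(seed, 301)),
                 rrna = rarefy(fl$rrna, depth, seed = sub_seed(seed, 302)))
      filtered[[s]] <- fl; rarefied[[s]] <- rr
      # joint clustering of both fractions, as in a combined dendrogram;
      # filtering is fraction-wise, so align on the union of OTU ids
      r1 <- relative_abundance(rr$rdna); r2 <- relative_abundance(rr$rrna)
      ids <- union(colnames(r1), colnames(r2))
      pad <- function(m) {
        out <- matrix(0, nrow(m), length(ids),
                      dimnames = list(rownames(m), ids))
        out[, colnames(m)] <- m
        out
      }
      rel <- rbind(pad(r1), pad(r2))
      d <- bray_curtis(rel)
      f1 <- file.path(odir, paste0(s, "_bray_curtis.tsv"))
      write_matrix_tsv(as.matrix(d), f1)
      f2 <- file.path(odir, paste0(s, "_dendrogram.nwk"))
      as_newick(hierarchical_cluster(d), f2)
      f3 <- file.path(odir, paste0(s, "_rarefied_rdna.tsv"))
      write_matrix_tsv(rr$rdna$counts, f3)
      f4 <- file.path(odir, paste0(s, "_rarefied_rrna.tsv"))
      write_matrix_tsv(rr$rrna$counts, f4)
      files <- c(files, f1, f2, f3, f4)
    }
    files
  })

  # stage: ecoplate ----------------------------------------------------
  profiles <- list()
  if (all(vapply(ds$sites, function(si) !is.null(si$aux$ecoplates), TRUE))) {
    edir <- file.path(out, "ecoplate"); dir.create(edir, showWarnings = FALSE)
    stage("ecoplate", {
      files <- character(0)
      for (s in names(ds$sites)) {
        pls <- ds$sites[[s]]$aux$ecoplates
        prof <- lapply(pls, normalize_plate)
        vals <- do.call(rbind, lapply(prof, `[[`, "values"))
        rownames(vals) <- names(pls)
        pres <- do.call(rbind, lapply(prof, `[[`, "presence")) * 1L
        rownames(pres) <- names(pls)
        profiles[[s]] <- vals
        f1 <- file.path(edir, paste0(s, "_profiles.tsv"))
        write_matrix_tsv(vals, f1, id_col = "month")
        f2 <- file.path(edir, paste0(s, "_presence.tsv"))
        write_matrix_tsv(pres, f2, id_col = "month")
        files <- c(files, f1, f2)
      }
      files
    })
  }

  # stage: stats -------------------------------------------------------
  if (length(profiles)) {
    sdir <- file.path(out, "stats"); dir.create(sdir, showWarnings = FALSE)
    stage("stats", {
      rows <- list()
      for (s in names(profiles)) {
        vals <- profiles[[s]]
        months <- as.integer(sub("^M", "", rownames(vals)))
        d_sub <- substrate_distances(vals, "euclidean")
        rel <- relative_abundance(rarefied[[s]]$rdna)
        rownames(rel) <- sprintf("M%02d", rarefied[[s]]$rdna$metadata$month)
        d_com <- bray_curtis(rel[rownames(vals), , drop = FALSE])
        mt <- mantel(d_sub, d_com,
                     n_perm = config$mantel_permutations %||% 9999,
                     seed = sub_seed(seed, 401))
        d_bc <- suppressWarnings(substrate_distances(vals, "bray_curtis"))
        quarter <- paste0("Q", (months - 1) %/% 3 + 1)
        pv <- permanova(d_bc, quarter,
                        n_perm = config$permanova_permutations %||% 999,
                        seed = sub_seed(seed, 402))
        rows[[s]] <- data.frame(
          site = s, mantel_r = mt$statistic, mantel_p = mt$p_value,
          permanova_f = pv$pseudo_f, permanova_r2 = pv$r_squared,
          permanova_p = pv$p_value)
      }
      f <- file.path(sdir, "substrate_stats.tsv")
      write.table(do.call(rbind, rows), f, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f
    })
  }

  # stage: rates -------------------------------------------------------
  if (all(vapply(ds$sites, function(si) !is.null(si$aux$doc), TRUE))) {
    rdir <- file.path(out, "rates"); dir.create(rdir, showWarnings = FALSE)
    stage("rates", {
      rows <- list(); grows <- list()
      for (s in names(ds$sites)) {
        aux <- ds$sites[[s]]$aux
        df <- fit_doc_decay(aux$doc$time, aux$doc$doc)
        rf <- respiration_rate(aux$o2)
        ss <- spectral_slope(aux$cdom$wavelength, aux$cdom$absorption,
                             range = c(275, 295))
        rows[[s]] <- data.frame(
          site = s, rdoc = df$rdoc, bdoc = df$bdoc, d_t = df$d_t,
          bdoc_percent = 100 * df$bdoc_fraction,
          doc_converged = df$converged,
          respiration_rate = rf$rate, respiration_se = rf$se,
          s275_295 = ss)
        g <- aux$growth
        grows[[s]] <- data.frame(
          site = s, month = g$month, bp_c = g$bp_c, br_c = g$br_c,
          bge_percent = bge(g$bp_c, g$br_c),
          cells_produced = cells_from_thymidine(g$thymidine_mol))
      }
      f1 <- file.path(rdir, "site_rates.tsv")
      write.table(do.call(rbind, rows), f1, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      f2 <- file.path(rdir, "growth.tsv")
      write.table(do.call(rbind, grows), f2, sep = "\t", quote = FALSE,
                  row.names = FALSE)
      c(f1, f2)
    })
  }

  # stage: drivers -----------------------------------------------------
  if (length(ds$sites) >= 2L) {
    ddir <- file.path(out, "drivers"); dir.create(ddir, showWarnings = FALSE)
    stage("drivers", {
      s12 <- names(ds$sites)[1:2]
      fns <- names(ds$sites[[s12[1]]]$functions)
      files <- character(0)
      info <- list()
      for (k in seq_along(fns)) {
        f <- fns[k]
        pms <- lapply(s12, function(s) {
          si <- ds$sites[[s]]
          assemble_predictors(filtered[[s]]$rdna, filtered[[s]]$rrna,
                              si$env, si$functions[[f]])
        })
        cons <- infer_function_drivers(
          pms[[1]], pms[[2]], seed = sub_seed(seed, 500 + k),
          k_folds = config$lasso$k_folds %||% NULL,
          rule = config$lasso$rule %||% "min",
          n_lambda = config$lasso$n_lambda %||% 40,
          function_name = f)
        fo <- file.path(ddir, paste0("drivers_", f, ".tsv"))
        write.table(as.data.frame(cons), fo, sep = "\t", quote = FALSE,
                    row.names = FALSE)
        files <- c(files, fo)
        info[[f]] <- list(lambda = as.list(attr(cons, "lambda")),
                          folds = attr(cons, "folds"),
                          n_consensus = nrow(cons))
      }
      fi <- file.path(ddir, "run_info.json")
      jsonlite::write_json(list(seed = seed, functions = info), fi,
                           auto_unbox = TRUE, digits = NA, pretty = TRUE)
      c(files, fi)
    })
  }

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(manifest)
}

#' Compare two run manifests for reproducibility
#'
#' Two runs agree when configuration, seed and every per-stage output
#' checksum match; wall-clock timings are ignored.
#'
#' @param m1,m2 manifests from [run_pipeline()] (or paths to
#'   `manifest.json`).
#' @return TRUE/FALSE.
#' @export
manifest_equal <- function(m1, m2) {
  norm <- function(m) {
    if (is.character(m)) m <- jsonlite::read_json(m)
    m$stages <- lapply(m$stages, function(s) s[["outputs"]])
    m
  }
  isTRUE(all.equal(norm(m1), norm(m2)))
}
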