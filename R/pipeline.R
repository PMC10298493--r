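#' Read a flat key=value configuration file
#'
#' Lines of the form \code{key = value}; blank lines and \code{#} comments
#' ignored. Values are kept as strings; consumers coerce.
#'
#' @param path config file.
#' @return named character vector.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    stop(config_error(paste("no such config file:", path)))
  ln <- trimws(readLines(path, warn = FALSE))
  ln <- ln[nzchar(ln) & !startsWith(ln, "#")]
  kv <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))
  bad <- vapply(kv, length, 0L) != 3L
  if (any(bad)) stop(config_error(paste("malformed config line:",
                                        ln[bad][1L])))
  stats::setNames(trimws(vapply(kv, `[`, "", 3L)),
                  trimws(vapply(kv, `[`, "", 2L)))
}

config_error <- function(msg)
  structure(class = c("felidelim_config_error", "error", "condition"),
            list(message = msg, call = NULL))

data_error <- function(msg)
  structure(class = c("felidelim_data_error", "error", "condition"),
            list(message = msg, call = NULL))

cfg_get <- function(cfg, key, default = NULL) {
  if (key %in% names(cfg)) cfg[[key]] else default
}

#' Run the full species-delimitation evidence chain
#'
#' Orchestrates the pipeline on one configuration: pairwise distances and
#' nearest-taxon / threshold evidence for a focal taxon (always), then
#' optionally haplotype-network dating, microsatellite clustering and
#' ordination, and diagnostic-site detection, depending on which inputs the
#' configuration provides. Stages without inputs are marked
#' \code{"skipped"}. Every numeric result is regenerable from the recorded
#' provenance block (inputs, seed, parameters, package version).
#'
#' Recognised keys: \code{focal} (required); \code{matrix} (distance CSV or
#' \code{builtin:table1}) with \code{matrix_dialect}; \code{alignment}
#' (FASTA, used for distances when no matrix is given, and for the network
#' and diagnosis stages); \code{exclude} (comma-separated labels);
#' \code{band_lower}, \code{band_upper} (percent, default 6 and 11);
#' \code{epsilon}; \code{ancestor}, \code{calendar_length},
#' \code{calendar_rate}, \code{calendar_override_ypm}; \code{genotypes}
#' (CSV), \code{bootstrap}; \code{diag_focal}, \code{reference},
#' \code{genes}; \code{seed}.
#'
#' @param config path to a key=value file, or a named list/vector.
#' @param out_json optional path: write the report as JSON (floats at 10
#'   significant digits).
#' @return a list of class \code{"analysis_report"}.
#' @export
run_delimitation <- function(config, out_json = NULL) {
  cfg <- if (is.character(config) && length(config) == 1L)
    read_config(config) else unlist(config)
  focal <- cfg_get(cfg, "focal")
  if (is.null(focal)) stop(config_error("config key 'focal' is required"))
  seed <- as.integer(cfg_get(cfg, "seed", 20230615))
  rep <- list(stages = list(), provenance = list(
    inputs = as.list(cfg), seed = seed,
    package_version = as.character(utils::packageVersion("felidelim"))))

  aln <- NULL
  if (!is.null(cfg_get(cfg, "alignment"))) {
    if (!file.exists(cfg[["alignment"]]))
      stop(data_error(paste("alignment file not found:",
                            cfg[["alignment"]])))
    aln <- read_fasta(cfg[["alignment"]])
  }

  # -- distance stage (required) --
  mspec <- cfg_get(cfg, "matrix")
  if (!is.null(mspec)) {
    m <- if (identical(mspec, "builtin:table1")) table1_fixture() else
      read_distance_matrix(mspec,
                           cfg_get(cfg, "matrix_dialect", "square-csv"))
  } else if (!is.null(aln)) {
    m <- k2p_matrix(aln)
  } else {
    stop(config_error(
      "distance stage needs a 'matrix' or 'alignment' input"))
  }
  if (!focal %in% m$labels)
    stop(data_error(paste("focal taxon", focal, "not in distance matrix")))
  excl <- cfg_get(cfg, "exclude", "")
  excl <- if (nzchar(excl)) trimws(strsplit(excl, ",")[[1L]]) else character()
  band <- threshold_band(as.numeric(cfg_get(cfg, "band_lower", 6)),
                         as.numeric(cfg_get(cfg, "band_upper", 11)),
                         context = "mitogenome")
  nt <- nearest_taxa(m, focal, exclude = excl)
  tr <- threshold_report(m, focal, band, exclude = excl)
  rep$stages$distances <- list(
    n_taxa = length(m$labels),
    undefined_pairs = nrow(m$undefined_pairs),
    nearest = nt[seq_len(min(5L, nrow(nt))), ],
    threshold_counts = as.list(tr$counts))

  # -- haplotype network / dating stage (optional) --
  anc <- cfg_get(cfg, "ancestor")
  if (!is.null(aln) && !is.null(anc)) {
    h <- collapse_haplotypes(aln)
    net <- build_mjn(h, epsilon = as.numeric(cfg_get(cfg, "epsilon", 0)))
    anc_lab <- net$labels[vapply(seq_along(net$labels), function(i)
      !net$is_median[i] && anc %in% h$members[[match(net$labels[i],
                                                     h$labels)]], TRUE)]
    if (length(anc_lab) != 1L)
      stop(data_error(paste("ancestor", anc, "not found in network")))
    cal <- mutation_rate_spec(
      rate = as.numeric(cfg_get(cfg, "calendar_rate", 1.22)),
      length = as.numeric(cfg_get(cfg, "calendar_length", aln$length)),
      years_per_mutation =
        if (is.null(cfg_get(cfg, "calendar_override_ypm"))) NULL else
          as.numeric(cfg[["calendar_override_ypm"]]))
    rh <- rho(net, anc_lab, calendar = cal)
    ds <- date_split(rh, cal)
    rep$stages$hapnet <- list(
      n_haplotypes = sum(!net$is_median),
      n_medians = sum(net$is_median), n_links = nrow(net$edges),
      rho = rh$rho, sigma = rh$sigma,
      years_per_mutation = cal$years_per_mutation,
      split_my = ds$time_my, split_error_my = ds$error_my)
  } else rep$stages$hapnet <- "skipped"

  # -- microsatellite stage (optional) --
  gpath <- cfg_get(cfg, "genotypes")
  if (!is.null(gpath)) {
    if (!file.exists(gpath))
      stop(data_error(paste("genotype file not found:", gpath)))
    g <- read_genotypes(gpath)
    f <- allele_freqs(g)
    dmu <- group_distance_matrix(f, "deltamu2")
    B <- as.integer(cfg_get(cfg, "bootstrap", 100))
    wt <- ward_tree(g, B = B, seed = seed)
    njt <- nj_tree(group_distance_matrix(f, "euclidean"))
    ord <- pcoa(dmu)
    ov <- pcoa_mst_overlay(ord, mst(dmu))
    rep$stages$msat <- list(
      n_individuals = length(g$individuals), n_loci = length(g$loci),
      groups = f$groups,
      deltamu2 = dmu$d,
      ward_newick = ape::write.tree(wt),
      nj_newick = ape::write.tree(njt),
      pcoa_axis_variance = ov_axis_var(ord),
      mst_edges = ov$edges)
  } else rep$stages$msat <- "skipped"

  # -- diagnosis stage (optional) --
  dfoc <- cfg_get(cfg, "diag_focal")
  if (!is.null(aln) && !is.null(dfoc)) {
    foc <- trimws(strsplit(dfoc, ",")[[1L]])
    genes <- if (is.null(cfg_get(cfg, "genes"))) NULL else
      read_gene_intervals(cfg[["genes"]])
    dg <- diagnostic_sites(aln, focal = foc,
                           reference = cfg_get(cfg, "reference", foc[1L]),
                           genes = genes)
    rep$stages$diagnosis <- list(n_sites = nrow(dg$sites),
                                 sites = dg$sites)
  } else rep$stages$diagnosis <- "skipped"

  class(rep) <- "analysis_report"
  if (!is.null(out_json)) {
    jsonlite::write_json(unclass(rep), out_json, auto_unbox = TRUE,
                         digits = 10, dataframe = "rows", pretty = TRUE,
                         force = TRUE)
  }
  rep
}

ov_axis_var <- function(ord)
  round(ord$percent_variance[seq_len(min(2L, length(ord$percent_variance)))],
        2)

#' @export
print.analysis_report <- function(x, ...) {
  cat("Species-delimitation report (focal:",
      x$provenance$inputs$focal, ")\n")
  for (s in names(x$stages)) {
    st <- x$stages[[s]]
    cat(" -", s, ":", if (identical(st, "skipped")) "skipped" else "run",
        "\n")
  }
  invisible(x)
}
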