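# Configuration handling and the umbrella pipeline:
# build-ensemble -> pucker -> geometry -> summary tables.

.config_keys <- c("seed", "out_dir", "n_frames", "temperature", "bin_width",
                  "write_frames", "frame_format", "chains", "residues")
.chain_keys <- c("chain", "n_frames", "mixtures", "torsion", "params", "Q",
                 "clash_radius", "max_retries")

# FNV-1a 32-bit hash of a string (provenance fingerprinting without extra
# dependencies)
fnv1a32 <- function(s) {
  bytes <- as.integer(charToRaw(s))
  h <- 2166136261
  p <- 16777619
  for (b in bytes) {
    # xor with the byte touches only the low 8 bits (h is kept as a double
    # in [0, 2^32), out of bitwXor's integer range)
    lo8 <- h %% 256
    h <- h - lo8 + bitwXor(as.integer(lo8), b)
    # 32-bit modular multiply, split to stay within double precision
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  # format as 8 hex digits (h may exceed the integer range, so by halves)
  paste0(sprintf("%04x", as.integer((h - h %% 65536) / 65536)),
         sprintf("%04x", as.integer(h %% 65536)))
}

#' Default demo configuration
#'
#' O-linked versus hemi-A S-linked heparosan decasaccharides
#' (`[GlcA-GlcNAc]_5` from the non-reducing end), 2000 frames each at
#' 298 K, with the GlcNAc chair mixture and the GlcA skew/boat admixture
#' configured as illustrative emulation presets (these weights are inputs,
#' not predictions).
#'
#' @param n_frames frames per chain.
#' @param seed RNG seed.
#' @return config list accepted by [run_pipeline()].
#' @export
demo_config <- function(n_frames = 2000, seed = 20221202) {
  olink <- format_chain(heparosan(5, slinked = FALSE))
  slink <- format_chain(heparosan(5, slinked = TRUE))
  list(
    seed = seed,
    n_frames = n_frames,
    temperature = 298,
    bin_width = 0.5,
    write_frames = FALSE,
    frame_format = "pdb",
    residues = "internal",
    chains = list(
      "O-linked" = list(
        chain = olink,
        mixtures = list(GlcNAc = c("4C1" = 0.999, "1C4" = 0.001),
                        GlcA = c("4C1" = 0.96, "1S5" = 0.01, "1S3" = 0.01,
                                 "1,4B" = 0.01, "B2,5" = 0.01))
      ),
      "S-linked" = list(
        chain = slink,
        mixtures = list(GlcNAc = c("4C1" = 0.40, "1C4" = 0.60),
                        GlcA = c("4C1" = 0.72, "1S5" = 0.07, "1S3" = 0.07,
                                 "1,4B" = 0.07, "B2,5" = 0.07))
      )
    )
  )
}

#' Read and validate a pipeline configuration
#'
#' JSON configuration with top-level keys `seed` (mandatory), `chains`
#' (named entries with a `chain` grammar string and optional `mixtures`,
#' `torsion`, `params`, `n_frames`, ...), and optional `n_frames`,
#' `temperature`, `bin_width`, `write_frames`, `frame_format`,
#' `residues`, `out_dir`.  Unknown keys are rejected.
#'
#' @param path JSON file path, or a config list to validate in place.
#' @return validated config list.
#' @export
read_config <- function(path) {
  cfg <- if (is.character(path)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    path
  }
  bad <- setdiff(names(cfg), .config_keys)
  if (length(bad) > 0) {
    stop("unknown configuration key(s): ", paste(bad, collapse = ", "))
  }
  if (is.null(cfg$seed)) stop("configuration is missing mandatory 'seed'")
  if (is.null(cfg$chains) || length(cfg$chains) == 0 ||
      is.null(names(cfg$chains))) {
    stop("configuration needs a named 'chains' table")
  }
  for (nm in names(cfg$chains)) {
    entry <- cfg$chains[[nm]]
    badc <- setdiff(names(entry), .chain_keys)
    if (length(badc) > 0) {
      stop("chain '", nm, "': unknown key(s): ", paste(badc, collapse = ", "))
    }
    if (is.null(entry$chain)) stop("chain '", nm, "' is missing 'chain'")
    parse_chain(entry$chain)  # validates grammar
    if (!is.null(entry$mixtures)) {
      cfg$chains[[nm]]$mixtures <- lapply(entry$mixtures, function(w) {
        if (is.list(w)) unlist(w) else w
      })
    }
  }
  if (is.null(cfg$n_frames)) cfg$n_frames <- 2000
  if (is.null(cfg$temperature)) cfg$temperature <- 298
  if (is.null(cfg$bin_width)) cfg$bin_width <- 0.5
  if (is.null(cfg$write_frames)) cfg$write_frames <- FALSE
  if (is.null(cfg$frame_format)) cfg$frame_format <- "pdb"
  if (is.null(cfg$residues)) cfg$residues <- "internal"
  cfg
}

write_csv_prov <- function(df, path, prov) {
  con <- file(path, "wb")  # binary: LF line endings on every platform
  on.exit(close(con))
  writeLines(prov, con, sep = "\n")
  lines <- c(paste(names(df), collapse = ","),
             do.call(paste, c(lapply(df, function(col) {
               if (is.numeric(col)) format(col, digits = 10, trim = TRUE,
                                           scientific = FALSE) else as.character(col)
             }), sep = ",")))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

tg_log <- function(..., quiet = FALSE) {
  if (!quiet) {
    message(format(Sys.time(), "[%Y-%m-%d %H:%M:%S] "), ...)
  }
}

#' Run the full analysis pipeline
#'
#' For every configured chain: builds the synthetic ensemble, computes
#' per-frame pucker states and conformer frequencies for the selected
#' residues, per-frame end-to-end and glycosidic geometry, and the
#' end-to-end histogram; writes one CSV per table plus a provenance JSON.
#' Outputs are deterministic given config + seed (byte-identical reruns).
#'
#' @param config config list or JSON path (see [read_config()]).
#' @param out_dir output directory (overrides the config's `out_dir`).
#' @param quiet suppress progress logging.
#' @return named list of output file paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir = NULL, quiet = FALSE) {
  cfg <- read_config(config)
  if (is.null(out_dir)) out_dir <- cfg$out_dir
  if (is.null(out_dir)) stop("no output directory given")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA)
  hash <- fnv1a32(as.character(cfg_json))
  prov <- sprintf("# thiogag %s | seed=%s | config=%s",
                  as.character(utils::packageVersion("thiogag")),
                  cfg$seed, hash)
  outputs <- list()
  for (nm in names(cfg$chains)) {
    entry <- cfg$chains[[nm]]
    tag <- gsub("[^A-Za-z0-9_.-]", "_", nm)
    tg_log("building ensemble '", nm, "'", quiet = quiet)
    spec <- ensemble_spec(
      chain = entry$chain,
      n_frames = if (!is.null(entry$n_frames)) entry$n_frames else cfg$n_frames,
      seed = cfg$seed,
      temperature = cfg$temperature,
      mixtures = if (is.null(entry$mixtures)) list() else entry$mixtures,
      params = if (is.null(entry$params)) list() else entry$params,
      torsion = if (is.null(entry$torsion)) list() else entry$torsion,
      Q = if (is.null(entry$Q)) 0.57 else entry$Q,
      clash_radius = if (is.null(entry$clash_radius)) 1.8 else entry$clash_radius,
      max_retries = if (is.null(entry$max_retries)) 50L else entry$max_retries
    )
    ens <- build_ensemble(spec)
    if (isTRUE(cfg$write_frames)) {
      fp <- file.path(out_dir, paste0(tag, ".", cfg$frame_format))
      write_frames(ens, fp, cfg$frame_format)
      outputs[[paste0(tag, "_frames")]] <- fp
    }
    tg_log("pucker analysis '", nm, "'", quiet = quiet)
    nres <- length(ens$chain$residues)
    sel <- if (identical(cfg$residues, "internal")) {
      internal_disaccharide(nres)
    } else if (identical(cfg$residues, "all")) seq_len(nres) else cfg$residues
    states <- list()
    for (ri in sel) {
      for (f in seq_along(ens$frames)) {
        ring <- extract_ring(ens$atoms, ens$frames[[f]], ri)
        st <- cremer_pople(ring)
        cc <- classify_conformer(st)
        pr <- sinusoidal_projection(st)
        states[[length(states) + 1]] <- data.frame(
          frame = f, residue = ri, Q = st$Q, theta = st$theta,
          phi = st$phi, label = cc$name, class = cc$class,
          x = pr$x, y = pr$y, stringsAsFactors = FALSE)
      }
    }
    per_frame <- do.call(rbind, states)
    p1 <- file.path(out_dir, paste0(tag, "_pucker.csv"))
    write_csv_prov(per_frame, p1, prov)
    freq <- pucker_frequencies(ens, residues = sel)
    p2 <- file.path(out_dir, paste0(tag, "_pucker_freq.csv"))
    write_csv_prov(freq, p2, prov)
    tg_log("geometry analysis '", nm, "'", quiet = quiet)
    e2e <- end_to_end(ens)
    gg <- glycosidic_geometry(ens)
    p3 <- file.path(out_dir, paste0(tag, "_endtoend.csv"))
    write_csv_prov(data.frame(frame = seq_along(e2e), end_to_end = e2e), p3, prov)
    p4 <- file.path(out_dir, paste0(tag, "_glycosidic.csv"))
    write_csv_prov(gg, p4, prov)
    hist <- length_histogram(e2e, bin_width = cfg$bin_width)
    p5 <- file.path(out_dir, paste0(tag, "_hist.csv"))
    write_csv_prov(hist, p5, prov)
    outputs[[tag]] <- c(pucker = p1, pucker_freq = p2, endtoend = p3,
                        glycosidic = p4, hist = p5)
  }
  prov_path <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(
    list(package = "thiogag",
         version = as.character(utils::packageVersion("thiogag")),
         r_version = paste(R.version$major, R.version$minor, sep = "."),
         seed = cfg$seed, config_hash = hash, config = cfg),
    prov_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  outputs$provenance <- prov_path
  tg_log("pipeline complete: ", out_dir, quiet = quiet)
  invisible(outputs)
}
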