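#' Simulate a chromosome with TAD and loop-anchor structure
#'
#' Generates a symmetric raw-count contact map from a power-law distance
#' decay modulated by TAD blocks and convergent loop anchors, with
#' multiplicative log-normal noise:
#' `counts[i,j] = base * (|i-j|+1)^-gamma * tad_boost^[same TAD] *
#' loop_boost^[within 1 bin of an anchor pair] * exp(eps)`,
#' `eps ~ N(0, noise_sd^2)`. TADs partition the chromosome into
#' (near-)equal blocks; each loop places a forward-motif anchor at the TAD's
#' first bins and a reverse-motif anchor at its last bins (convergent
#' orientation), nested loops being inset by two bins.
#'
#' @param n_bins Number of bins (`>= 50`). Default 300.
#' @param resolution Bin size in bp. Default 10000.
#' @param n_tads Number of TADs. Default 6.
#' @param loops_per_tad Convergent loops per TAD. Default 1.
#' @param gamma Distance-decay exponent (> 0). Default 0.8.
#' @param tad_boost,loop_boost Multiplicative enrichments (`>= 1`).
#'   Defaults 3 and 5.
#' @param noise_sd Log-normal noise sd. Default 0.3.
#' @param base Count scale at the diagonal. Default 100.
#' @param seed Integer seed. Default 7.
#' @return List with `contacts` (a raw-count [contact_matrix()]) and
#'   `truth` (class `synthetic_truth`: TAD intervals in bp, anchor bin
#'   pairs with orientations, boundary bins, and all parameters).
#' @export
generate_chromosome <- function(n_bins = 300L, resolution = 10000,
                                n_tads = 6L, loops_per_tad = 1L,
                                gamma = 0.8, tad_boost = 3, loop_boost = 5,
                                noise_sd = 0.3, base = 100, seed = 7L) {
  if (n_bins < 50) stop("n_bins must be >= 50")
  if (gamma <= 0) stop("gamma must be > 0")
  if (tad_boost < 1 || loop_boost < 1) stop("boost factors must be >= 1")
  if (noise_sd < 0 || base <= 0 || n_tads < 1 || loops_per_tad < 0)
    stop("invalid simulation parameters")
  n_bins <- as.integer(n_bins)

  # near-equal TAD partition (deterministic given n_bins, n_tads)
  cuts <- round(seq(0, n_bins, length.out = n_tads + 1))
  tad_start <- cuts[-length(cuts)]        # 0-based first bin
  tad_end <- cuts[-1]                     # exclusive
  tad_of <- rep(seq_len(n_tads), times = tad_end - tad_start)

  anchors <- NULL
  for (td in seq_len(n_tads)) {
    for (l in seq_len(loops_per_tad)) {
      inset <- 2L * (l - 1L)
      a <- tad_start[td] + inset
      b <- tad_end[td] - 1L - inset
      if (b - a < 3) next
      anchors <- rbind(anchors,
                       data.frame(tad = td, left = a, right = b,
                                  left_strand = "+", right_strand = "-"))
    }
  }

  d <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  m <- base * (d + 1)^(-gamma)
  same_tad <- outer(tad_of, tad_of, "==")
  m <- m * ifelse(same_tad, tad_boost, 1)
  if (!is.null(anchors)) {
    for (r in seq_len(nrow(anchors))) {
      ii <- pmax(1L, anchors$left[r]):pmin(n_bins, anchors$left[r] + 2L)
      jj <- pmax(1L, anchors$right[r]):pmin(n_bins, anchors$right[r] + 2L)
      m[ii, jj] <- m[ii, jj] * loop_boost
      m[jj, ii] <- m[jj, ii] * loop_boost
    }
  }
  if (noise_sd > 0) {
    eps <- with_seed(seed, matrix(stats::rnorm(n_bins^2, sd = noise_sd),
                                  n_bins, n_bins))
    eps[lower.tri(eps)] <- t(eps)[lower.tri(eps)]
    m <- m * exp(eps)
  }

  truth <- structure(
    list(tads = data.frame(start = tad_start * resolution,
                           end = tad_end * resolution),
         anchors = anchors,
         boundary_bins = sort(unique(c(tad_start, tad_end - 1L))),
         gamma = gamma, tad_boost = tad_boost, loop_boost = loop_boost,
         noise_sd = noise_sd, base = base, seed = as.integer(seed),
         n_bins = n_bins, resolution = resolution),
    class = "synthetic_truth")
  list(contacts = contact_matrix(m, resolution, "raw_counts"), truth = truth)
}

#' @export
print.synthetic_truth <- function(x, ...) {
  cat(sprintf("synthetic_truth: %d bins at %g bp, %d TADs, %d loop(s), gamma %g, seed %d\n",
              x$n_bins, x$resolution, nrow(x$tads),
              if (is.null(x$anchors)) 0L else nrow(x$anchors), x$gamma, x$seed))
  invisible(x)
}

#' Write a simulated chromosome as a file fixture
#'
#' Emits the contact list in juicer-dump text, TADs / anchor bins (with
#' strand) / boundary bins as BED, and the generator parameters as JSON, so
#' the whole pipeline can be exercised from files alone.
#'
#' @param sim The list returned by [generate_chromosome()].
#' @param out_dir Output directory (created if needed).
#' @param chrom Chromosome name used in the BED files. Default `"chrS"`.
#' @return Named character vector of the files written.
#' @export
write_fixture <- function(sim, out_dir, chrom = "chrS") {
  stopifnot(is.list(sim), inherits(sim$contacts, "contact_matrix"),
            inherits(sim$truth, "synthetic_truth"))
  if (!dir.exists(out_dir) &&
      !dir.create(out_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory: ", out_dir)
  tr <- sim$truth
  res <- sim$contacts$resolution
  paths <- c(contacts = file.path(out_dir, "contacts.txt"),
             tads = file.path(out_dir, "tads.bed"),
             anchors = file.path(out_dir, "anchors.bed"),
             boundaries = file.path(out_dir, "boundaries.bed"),
             params = file.path(out_dir, "params.json"))
  write_contacts(sim$contacts, paths[["contacts"]])
  write_bed(data.frame(start = tr$tads$start, end = tr$tads$end,
                       name = paste0("TAD", seq_len(nrow(tr$tads)))),
            paths[["tads"]], chrom = chrom)
  if (!is.null(tr$anchors)) {
    anc <- rbind(
      data.frame(start = tr$anchors$left * res,
                 end = (tr$anchors$left + 1) * res,
                 name = paste0("loop", seq_len(nrow(tr$anchors)), "_L"),
                 strand = tr$anchors$left_strand),
      data.frame(start = tr$anchors$right * res,
                 end = (tr$anchors$right + 1) * res,
                 name = paste0("loop", seq_len(nrow(tr$anchors)), "_R"),
                 strand = tr$anchors$right_strand))
    write_bed(anc[order(anc$start), ], paths[["anchors"]], chrom = chrom)
  }
  write_bed(data.frame(start = tr$boundary_bins * res,
                       end = (tr$boundary_bins + 1) * res,
                       name = paste0("b", seq_along(tr$boundary_bins))),
            paths[["boundaries"]], chrom = chrom)
  jsonlite::write_json(
    tr[c("gamma", "tad_boost", "loop_boost", "noise_sd", "base", "seed",
         "n_bins", "resolution")],
    paths[["params"]], auto_unbox = TRUE, digits = NA)
  paths
}
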