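#' Describe a synthetic SNP panel
#'
#' The generative world: a domesticated query genome that is a mosaic of
#' low-divergence background and planted donor-derived segments, an
#' introgression-free heirloom line, and one or more wild donors, all called
#' against the same reference coordinate space. Donor SNPs are placed by a
#' per-bp Poisson process at the donor's divergence rate; inside
#' `reference_segments` the reference itself carries the donor's sequence, so
#' both the query and the heirloom show the donor's SNPs there (the signature
#' used to flag reference-genome introgressions).
#'
#' Default rates are anchored to published whole-genome divergence figures
#' for tomato: 0.35% for *S. pimpinellifolium* and 1% for *S. chilense*
#' versus the reference. The domesticated background uses 3.7e-5/bp, an
#' order of magnitude below the 0.037% genome-wide figure for an inbred
#' line, because that printed rate averages over its introgressions (the
#' majority of such a line's SNPs sit inside them); see the methods vignette.
#'
#' @param index a [genome_index()].
#' @param background_rate SNPs/bp of the domesticated background (default
#'   3.7e-5).
#' @param donor_rates named SNPs/bp per donor (defaults: pimpinellifolium
#'   3.5e-3, chilense 1e-2).
#' @param query_segments,reference_segments data.frames
#'   (`chrom, start, end, donor`), 0-based half-open, non-overlapping.
#' @param depth_mean mean simulated read depth (default 30).
#' @param het_fraction fraction of calls given heterozygous-like allele
#'   fractions near 0.5 (default 0.02), exercising the allele-fraction
#'   filter.
#' @param seed master seed; every (accession, chromosome) derives its own
#'   substream so adding an accession never perturbs the others.
#' @param query_id,heirloom_id accession labels.
#' @return A `simulation_spec` list.
#' @export
simulation_spec <- function(index,
                            background_rate = 3.7e-5,
                            donor_rates = c(pimpinellifolium = 3.5e-3,
                                            chilense = 1e-2),
                            query_segments = NULL,
                            reference_segments = NULL,
                            depth_mean = 30, het_fraction = 0.02,
                            seed = 1L,
                            query_id = "query", heirloom_id = "heirloom") {
  stopifnot(inherits(index, "genome_index"))
  seg_dt <- function(x) {
    if (is.null(x) || !NROW(x))
      return(data.table(chrom = character(), start = numeric(),
                        end = numeric(), donor = character()))
    as.data.table(x)[, .(chrom = as.character(chrom),
                         start = as.numeric(start), end = as.numeric(end),
                         donor = as.character(donor))]
  }
  qs <- seg_dt(query_segments); rs <- seg_dt(reference_segments)
  rates <- c(background = unname(background_rate), donor_rates)
  if (any(rates <= 0 | rates > 0.05))
    param_error("all SNP rates must lie in (0, 0.05]")
  all_seg <- rbind(qs, rs)
  if (nrow(all_seg)) {
    if (!all(all_seg$donor %in% names(donor_rates)))
      abort("introscan_spec_error", "segment donor not in donor_rates")
    lens <- chrom_length(index, all_seg$chrom)
    if (any(all_seg$start < 0 | all_seg$end > lens |
            all_seg$start >= all_seg$end))
      abort("introscan_spec_error", "planted segment outside chromosome")
    o <- all_seg[order(chrom, start)]
    if (any(o[, .N > 1 && any(start[-1] < head(end, -1)), by = chrom]$V1))
      abort("introscan_spec_error", "planted segments overlap")
  }
  spec <- list(index = index, background_rate = background_rate,
               donor_rates = donor_rates, query_segments = qs,
               reference_segments = rs, depth_mean = depth_mean,
               het_fraction = het_fraction, seed = as.integer(seed),
               query_id = query_id, heirloom_id = heirloom_id)
  class(spec) <- "simulation_spec"
  spec
}

#' The package's default stated world
#'
#' One 20-Mb chromosome; five query introgressions of 0.1-2 Mb from a
#' chilense-like donor (1e-2 SNPs/bp), two reference-genome introgressions
#' from a pimpinellifolium-like donor (3.5e-3 SNPs/bp), domesticated
#' background 3.7e-5 SNPs/bp, depth 30x.
#'
#' @param seed master seed.
#' @return A [simulation_spec()].
#' @export
default_simulation_spec <- function(seed = 1L) {
  gi <- genome_index("ch01", 2e7)
  qs <- data.table(
    chrom = "ch01",
    start = c(1003500, 3250000, 6000000, 10400000, 13500000),
    end   = c(1151200, 3350000, 8000000, 10700000, 14200000),
    donor = "chilense")
  rs <- data.table(
    chrom = "ch01",
    start = c(16000000, 18200000),
    end   = c(16800000, 18650000),
    donor = "pimpinellifolium")
  simulation_spec(gi, query_segments = qs, reference_segments = rs,
                  seed = seed)
}

# Deterministic reference base at a position (consistent across accessions).
ref_allele_at <- function(chrom, pos) {
  nuc <- c("A", "C", "G", "T")
  h <- vapply(unique(chrom), str_hash31, 0)[chrom]
  nuc[((h + pos * 1103515245 + 12345) %% 4) + 1]
}

# Poisson-placed substitutions on one chromosome at `rate`, drawn from the
# current RNG stream. Returns 0-based positions with ref/alt alleles.
place_snps <- function(chrom, len, rate) {
  n <- min(rpois(1, rate * len), len)
  if (n == 0)
    return(data.table(chrom = character(), pos = numeric(),
                      ref = character(), alt = character()))
  pos <- sort(sample.int(len, n)) - 1
  ref <- ref_allele_at(rep(chrom, n), pos)
  nuc <- c("A", "C", "G", "T")
  shift <- sample.int(3, n, replace = TRUE)
  alt <- nuc[((match(ref, nuc) - 1 + shift) %% 4) + 1]
  data.table(chrom = chrom, pos = pos, ref = ref, alt = alt)
}

in_segments <- function(dt, segs) {
  if (!nrow(dt) || !nrow(segs)) return(rep(FALSE, nrow(dt)))
  hit <- rep(FALSE, nrow(dt))
  for (i in seq_len(nrow(segs)))
    hit <- hit | (dt$chrom == segs$chrom[i] & dt$pos >= segs$start[i] &
                    dt$pos < segs$end[i])
  hit
}

#' Simulate a multi-accession SNP panel with planted introgressions
#'
#' Generates, per the spec: donor accessions with genome-wide Poisson SNPs at
#' their divergence rates; a heirloom with background-rate private SNPs plus
#' the donor's SNPs inside planted reference segments; and a query with
#' background SNPs outside all planted segments, the donor's SNPs inside its
#' planted query segments, and the donor's SNPs inside reference segments
#' (there shared with the heirloom). Depths are Poisson around `depth_mean`;
#' allele fractions are near 1 for homozygous inbred calls with a small
#' heterozygous-contamination fraction. Fully reproducible from the spec's
#' seed.
#'
#' @param spec a [simulation_spec()].
#' @return list with `accessions` (named list of [snp_records()], query and
#'   heirloom first, then donors), `truth` (planted query/reference segment
#'   tables) and `spec`.
#' @export
simulate_panel <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  gi <- spec$index
  donors <- names(spec$donor_rates)

  gen_genome <- function(label, rate) {
    rbindlist(lapply(seq_len(nrow(gi)), function(i)
      with_local_seed(substream_seed(spec$seed, label, gi$chrom[i]),
                      place_snps(gi$chrom[i], gi$length[i], rate))))
  }

  donor_snps <- lapply(donors, function(d)
    gen_genome(paste0("donor:", d), spec$donor_rates[[d]]))
  names(donor_snps) <- donors

  planted_from <- function(segs) {
    if (!nrow(segs))
      return(data.table(chrom = character(), pos = numeric(),
                        ref = character(), alt = character()))
    rbindlist(lapply(seq_len(nrow(segs)), function(i) {
      d <- donor_snps[[segs$donor[i]]]
      d[chrom == segs$chrom[i] & pos >= segs$start[i] & pos < segs$end[i]]
    }))
  }

  all_planted <- rbind(spec$query_segments, spec$reference_segments)
  heir_bg <- gen_genome(spec$heirloom_id, spec$background_rate)
  query_bg <- gen_genome(spec$query_id, spec$background_rate)
  query_bg <- query_bg[!in_segments(query_bg, all_planted)]

  heir <- rbind(planted_from(spec$reference_segments), heir_bg)
  query <- rbind(planted_from(spec$query_segments),
                 planted_from(spec$reference_segments), query_bg)
  # inherited donor records win over colliding background positions
  dedupe <- function(dt) unique(dt, by = c("chrom", "pos"))
  heir <- dedupe(heir); query <- dedupe(query)

  finish <- function(dt, label) {
    dt <- dt[order(match(chrom, gi$chrom), pos)]
    n <- nrow(dt)
    if (n) {
      parts <- lapply(unique(dt$chrom), function(ch) {
        sub <- dt[chrom == ch]
        with_local_seed(substream_seed(spec$seed, "depth", label, ch), {
          dp <- pmax(1L, rpois(nrow(sub), spec$depth_mean))
          het <- runif(nrow(sub)) < spec$het_fraction
          ad_alt <- rbinom(nrow(sub), dp, fifelse(het, 0.5, 0.99))
          sub[, `:=`(depth = as.numeric(dp),
                     alt_fraction = ad_alt / dp,
                     ad_ref = dp - ad_alt, ad_alt = ad_alt)]
        })
        sub
      })
      dt <- rbindlist(parts)
    } else dt[, `:=`(depth = numeric(), alt_fraction = numeric(),
                     ad_ref = numeric(), ad_alt = numeric())]
    out <- snp_records(label, dt$chrom, dt$pos, dt$ref, dt$alt,
                       dt$depth, dt$alt_fraction)
    out[, `:=`(ad_ref = dt$ad_ref, ad_alt = dt$ad_alt)]
    normalize_snps(out, gi)
  }

  accs <- c(setNames(list(finish(query, spec$query_id)), spec$query_id),
            setNames(list(finish(heir, spec$heirloom_id)), spec$heirloom_id),
            setNames(lapply(donors, function(d)
              finish(donor_snps[[d]], d)), donors))
  list(accessions = accs,
       truth = list(query_segments = copy(spec$query_segments),
                    reference_segments = copy(spec$reference_segments)),
       spec = spec)
}

#' Write a simulated panel as per-accession VCFs plus truth files
#'
#' Emits one VCF v4.2 per accession (single sample, `GT:DP:AD`), truth BED
#' files (`query_truth.bed`, `reference_truth.bed`), the genome index as TSV
#' and the spec echoed as JSON. Output bytes are a pure function of the spec.
#'
#' @param panel result of [simulate_panel()].
#' @param out_dir output directory (created if needed).
#' @return named character vector of the files written, invisibly.
#' @export
emit_vcfs <- function(panel, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  spec <- panel$spec
  gi <- spec$index
  files <- c()
  for (acc in names(panel$accessions)) {
    snps <- panel$accessions[[acc]]
    path <- file.path(out_dir, paste0(acc, ".vcf"))
    hdr <- c("##fileformat=VCFv4.2",
             "##source=introscan-simulator",
             sprintf("##contig=<ID=%s,length=%d>", gi$chrom,
                     as.integer(gi$length)),
             "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
             "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
             "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
             paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                    acc))
    con <- file(path, open = "wb")   # binary: LF endings on any platform
    writeLines(hdr, con, sep = "\n")
    if (nrow(snps)) {
      has_ad <- all(c("ad_ref", "ad_alt") %in% names(snps))
      gt <- fifelse(!is.na(snps$alt_fraction) & snps$alt_fraction < 0.9,
                    "0/1", "1/1")
      fmt <- if (has_ad)
        sprintf("%s:%d:%d,%d", gt, as.integer(snps$depth),
                as.integer(snps$ad_ref), as.integer(snps$ad_alt))
      else sprintf("%s:%d", gt, as.integer(snps$depth))
      lines <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\t%s\t%s",
                       snps$chrom, as.integer(snps$pos) + 1L, snps$ref,
                       snps$alt, if (has_ad) "GT:DP:AD" else "GT:DP", fmt)
      writeLines(lines, con, sep = "\n")
    }
    close(con)
    files[paste0("vcf_", acc)] <- path
  }
  truth_bed <- function(segs, path) {
    con <- file(path, open = "wb")
    writeLines("#chrom\tstart\tend\tdonor", con, sep = "\n")
    if (nrow(segs))
      writeLines(sprintf("%s\t%d\t%d\t%s", segs$chrom,
                         as.integer(segs$start), as.integer(segs$end),
                         segs$donor), con, sep = "\n")
    close(con)
    path
  }
  files["query_truth"] <- truth_bed(spec$query_segments,
                                    file.path(out_dir, "query_truth.bed"))
  files["reference_truth"] <- truth_bed(
    spec$reference_segments, file.path(out_dir, "reference_truth.bed"))
  files["genome_index"] <- write_genome_index(
    gi, file.path(out_dir, "genome_index.tsv"))
  cfg <- spec[c("background_rate", "donor_rates", "depth_mean",
                "het_fraction", "seed", "query_id", "heirloom_id")]
  cfg$chromosomes <- as.data.frame(gi)
  cfg$query_segments <- as.data.frame(spec$query_segments)
  cfg$reference_segments <- as.data.frame(spec$reference_segments)
  jsonlite::write_json(cfg, file.path(out_dir, "simulation_config.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  files["config"] <- file.path(out_dir, "simulation_config.json")
  invisible(files)
}
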