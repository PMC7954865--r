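# Nearest-gene assignment, proto-oncogene locus surveillance, and
# longitudinal clone tracking against a sequencing-noise floor.

#' Read gene annotations from BED
#'
#' BED6 (0-based half-open) gene models via `rtracklayer`; coordinates are
#' converted to 1-based inclusive on import. The transcription start site
#' (TSS) is the start for `+` genes and the end for `-` genes.
#'
#' @param path BED file path.
#' @return Data frame: `name`, `chrom`, `start`, `end`, `strand`, `tss`
#'   (1-based).
#' @export
read_gene_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "BED")
  df <- as.data.frame(gr)
  if (is.null(df$name) || anyNA(df$name)) {
    stop(path, ": BED name column (gene symbol) required", call. = FALSE)
  }
  strand <- as.character(df$strand)
  if (any(!strand %in% c("+", "-"))) {
    stop(path, ": gene strand must be '+' or '-' to orient the TSS",
         call. = FALSE)
  }
  data.frame(name = df$name,
             chrom = as.character(df$seqnames),
             start = df$start, end = df$end, strand = strand,
             tss = ifelse(strand == "+", df$start, df$end),
             stringsAsFactors = FALSE)
}

#' Assign the single nearest gene to each IS
#'
#' The nearest gene is the one minimising the distance from the IS position
#' to its TSS, within `max_distance` (1 Mb by default); an IS falling
#' inside a gene body is assigned to that gene at distance 0. Ties are
#' broken by lexicographic gene name. The signed distance is oriented by
#' gene strand: positive downstream of the TSS (into the gene), negative
#' upstream.
#'
#' @param is_pos data frame with `chrom` and `pos` (1-based) columns — e.g.
#'   IS records or [is_info()] of a matrix.
#' @param genes gene table from [read_gene_bed()].
#' @param max_distance maximum IS-to-TSS distance in bp; farther IS stay
#'   unassigned.
#' @return Data frame aligned with `is_pos`: `gene` (NA when unassigned),
#'   `distance` (signed; NA when unassigned), `reason` (why unassigned).
#' @export
nearest_gene <- function(is_pos, genes, max_distance = 1e6) {
  if (nrow(genes) == 0) stop("empty gene annotation", call. = FALSE)
  gene <- rep(NA_character_, nrow(is_pos))
  dist <- rep(NA_real_, nrow(is_pos))
  reason <- rep(NA_character_, nrow(is_pos))
  for (i in seq_len(nrow(is_pos))) {
    g <- genes[genes$chrom == is_pos$chrom[i], , drop = FALSE]
    if (nrow(g) == 0) {
      reason[i] <- "chromosome absent from annotation"
      next
    }
    pos <- is_pos$pos[i]
    inside <- g$start <= pos & pos <= g$end
    if (any(inside)) {
      nm <- sort(g$name[inside])[1L]
      gene[i] <- nm
      dist[i] <- 0
      next
    }
    d_abs <- abs(pos - g$tss)
    if (min(d_abs) > max_distance) {
      reason[i] <- sprintf("no TSS within %g bp", max_distance)
      next
    }
    best <- which(d_abs == min(d_abs))
    best <- best[order(g$name[best])][1L]
    gene[i] <- g$name[best]
    dist[i] <- if (g$strand[best] == "+") pos - g$tss[best]
               else g$tss[best] - pos
  }
  data.frame(gene = gene, distance = dist, reason = reason,
             stringsAsFactors = FALSE)
}

.abundance_class <- function(pct) {
  # lower boundary inclusive: exactly 1% is "<=1%", exactly 10% is "1-10%"
  cut(pct, breaks = c(-Inf, 1, 10, Inf),
      labels = c("<1%", "1-10%", ">10%"), right = TRUE)
}

#' Flag IS near proto-oncogenes under insertional-mutagenesis surveillance
#'
#' Every IS whose nearest gene is one of the watched loci (by default the
#' three proto-oncogenes historically involved in vector
#' insertional-mutagenesis events: LMO2, MECOM, CCND2), with its maximum
#' relative abundance over all samples and its abundance class relative to
#' the 1% and 10% surveillance thresholds.
#'
#' @param m an [build_matrix()] abundance matrix.
#' @param genes gene table from [read_gene_bed()].
#' @param loci gene names to watch.
#' @param max_distance nearest-gene cutoff in bp.
#' @return Data frame: `is_key`, `gene`, `distance`, `max_abundance_pct`,
#'   `class` (one of `<1%`, `1-10%`, `>10%`), `max_sample`.
#' @export
flag_oncogenes <- function(m, genes, loci = c("LMO2", "MECOM", "CCND2"),
                           max_distance = 1e6) {
  ann <- nearest_gene(is_info(m), genes, max_distance = max_distance)
  hit <- which(!is.na(ann$gene) & ann$gene %in% loci)
  if (length(hit) == 0) {
    return(data.frame(is_key = character(), gene = character(),
                      distance = numeric(), max_abundance_pct = numeric(),
                      class = character(), max_sample = character(),
                      stringsAsFactors = FALSE))
  }
  pct <- relative_abundance(m)
  rows <- lapply(hit, function(i) {
    j <- which.max(pct[i, ])
    data.frame(is_key = rownames(m)[i], gene = ann$gene[i],
               distance = ann$distance[i],
               max_abundance_pct = pct[i, j],
               class = as.character(.abundance_class(pct[i, j])),
               max_sample = colnames(m)[j],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$gene, -out$max_abundance_pct), , drop = FALSE]
}

#' Track one clone's relative abundance across samples
#'
#' Per-sample relative abundance of one IS with a detection class per
#' sample: `undetected` (0 reads), `sub-noise` (abundance at or below the
#' sequencing noise floor, 0.0001% by default — single-read signal in a
#' deeply sequenced library), or `detected`.
#'
#' @param m an abundance matrix.
#' @param is_key IS identity key `chrom:pos:strand` (a rowname of `m`).
#' @param noise_floor noise floor in percent.
#' @return Data frame, one row per sample in column order: `sample`,
#'   `patient`, `compartment`, `timepoint_months`, `reads`,
#'   `abundance_pct`, `class`.
#' @export
track_clone <- function(m, is_key, noise_floor = 1e-4) {
  if (!is_key %in% rownames(m)) {
    stop("IS not present in matrix: ", is_key, call. = FALSE)
  }
  pct <- relative_abundance(m)[is_key, ]
  cls <- ifelse(pct == 0, "undetected",
                ifelse(pct <= noise_floor, "sub-noise", "detected"))
  cbind(data.frame(sample = colnames(m), stringsAsFactors = FALSE),
        sample_info(m),
        data.frame(reads = unclass(m)[is_key, ], abundance_pct = pct,
                   class = cls, row.names = NULL,
                   stringsAsFactors = FALSE))
}
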