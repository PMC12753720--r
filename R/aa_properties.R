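# Physicochemical scales for the 20 standard amino acids. Each scale is a
# named numeric vector so alternative tables can be swapped in by the caller.

#' Amino-acid property scales
#'
#' Named lookup tables used by [compute_cdr3_properties()]:
#' * `gravy` — Kyte–Doolittle hydropathy.
#' * `bulk` — Zimmerman bulkiness.
#' * `polarity` — Grantham polarity.
#' * `pk` — EMBOSS side-chain pKa values used for net charge.
#'
#' @format A named list of named numeric vectors keyed by one-letter code.
#' @export
aa_scales <- list(
  gravy = c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
            Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
            L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
            S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2),
  bulk  = c(A = 11.50, R = 14.28, N = 12.82, D = 11.68, C = 13.46,
            Q = 14.45, E = 13.57, G =  3.40, H = 13.69, I = 21.40,
            L = 21.40, K = 15.71, M = 16.25, F = 19.80, P = 17.43,
            S =  9.47, T = 15.77, W = 21.67, Y = 18.03, V = 21.57),
  polarity = c(A =  8.1, R = 10.5, N = 11.6, D = 13.0, C =  5.5,
               Q = 10.5, E = 12.3, G =  9.0, H = 10.4, I =  5.2,
               L =  4.9, K = 11.3, M =  5.7, F =  5.2, P =  8.0,
               S =  9.2, T =  8.6, W =  5.4, Y =  6.2, V =  5.9),
  # EMBOSS pKa values; termini are excluded from the charge computation.
  pk = c(C = 8.5, D = 3.9, E = 4.1, H = 6.5, K = 10.8, R = 12.5, Y = 10.1)
)

AA_LETTERS <- names(aa_scales$gravy)

# Per-residue contribution tables; a peptide property is the mean (or sum
# divided by length) of these over its residues, which is what makes the
# bulk computation in compute_cdr3_properties() a single rowsum pass.
aa_residue_tables <- function(ph = 7.4) {
  pos <- c("R", "H", "K")
  neg <- c("D", "E", "C", "Y")
  charge <- setNames(numeric(20), AA_LETTERS)
  charge[pos] <- 1 / (1 + 10^(ph - aa_scales$pk[pos]))
  charge[neg] <- -1 / (1 + 10^(aa_scales$pk[neg] - ph))
  aliph <- setNames(numeric(20), AA_LETTERS)
  aliph[c("A", "V", "I", "L")] <- c(1, 2.9, 3.9, 3.9)
  list(
    gravy     = aa_scales$gravy,
    bulk      = aa_scales$bulk,
    aliphatic = aliph,
    polarity  = aa_scales$polarity,
    charge    = charge,
    acidic    = setNames(as.numeric(AA_LETTERS %in% c("D", "E")), AA_LETTERS),
    basic     = setNames(as.numeric(AA_LETTERS %in% c("R", "H", "K")), AA_LETTERS),
    aromatic  = setNames(as.numeric(AA_LETTERS %in% c("F", "W", "H", "Y")), AA_LETTERS)
  )
}

#' Per-peptide physicochemical properties
#'
#' Computes the nine CDR3 properties for a vector of amino-acid strings:
#' `length`, `gravy` (Kyte–Doolittle mean), `bulk` (Zimmerman mean),
#' `aliphatic` (Ikai aliphatic index on mole fractions, coefficients 2.9 for
#' Val and 3.9 for Ile/Leu), `polarity` (Grantham mean), `charge` (net
#' side-chain charge at `ph` via Henderson–Hasselbalch with EMBOSS pKa,
#' termini excluded), and the `acidic` (D/E), `basic` (R/H/K) and `aromatic`
#' (F/W/H/Y) residue fractions.
#'
#' Peptides containing characters outside the 20 standard one-letter codes,
#' or empty strings, yield `NA` for every property (their `length` is still
#' reported).
#'
#' @param peptides character vector of amino-acid sequences.
#' @param ph pH at which net charge is evaluated (default 7.4).
#' @return data.frame with one row per peptide and columns
#'   `length, gravy, bulk, aliphatic, polarity, charge, acidic, basic, aromatic`.
#' @export
peptide_properties <- function(peptides, ph = 7.4) {
  stopifnot(is.character(peptides))
  n <- length(peptides)
  len <- nchar(peptides)
  out <- data.frame(length = as.numeric(len),
                    gravy = NA_real_, bulk = NA_real_, aliphatic = NA_real_,
                    polarity = NA_real_, charge = NA_real_, acidic = NA_real_,
                    basic = NA_real_, aromatic = NA_real_)
  if (n == 0L) return(out)
  tabs <- aa_residue_tables(ph)
  # one pass over all residues: map characters to 0..25 codes, then rowsum
  codes <- utf8ToInt(paste(peptides, collapse = ""))
  grp <- rep.int(seq_len(n), len)
  lookup <- function(tab) {
    v <- rep(NA_real_, 128)
    v[utf8ToInt(paste(AA_LETTERS, collapse = "")) + 1L] <- tab
    v
  }
  valid_codes <- utf8ToInt(paste(AA_LETTERS, collapse = "")) + 1L
  ok_res <- (codes + 1L) %in% valid_codes
  # a peptide is eligible only if non-empty and all residues standard
  bad <- rep(FALSE, n)
  if (any(!ok_res)) bad[unique(grp[!ok_res])] <- TRUE
  bad[len == 0L] <- TRUE
  if (!all(bad)) {
    keep <- !bad[grp]
    g <- grp[keep]
    cd <- codes[keep] + 1L
    for (prop in names(tabs)) {
      v <- lookup(tabs[[prop]])
      sums <- rowsum(v[cd], g)
      idx <- as.integer(rownames(sums))
      out[[prop]][idx] <- sums[, 1] / len[idx]
    }
    # net charge is a sum, not a mean
    v <- lookup(tabs$charge)
    sums <- rowsum(v[codes[keep] + 1L], g)
    idx <- as.integer(rownames(sums))
    out$charge[idx] <- sums[, 1]
  }
  out
}
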