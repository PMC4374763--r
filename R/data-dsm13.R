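# Published study inputs for the B. licheniformis DSM13 prophage
# system: region table, sequencing coverage summaries, and control
# primers. These are inputs to the workflow's arithmetic (coordinate
# conventions, signal-to-noise formulas), not results it computes.

#' Prophage regions of *B. licheniformis* DSM13
#'
#' The seven annotated prophage regions BLi_Pp1 -- BLi_Pp7 on the DSM13
#' chromosome (accession AE017333.1, 1-based inclusive coordinates),
#' with their GC content, reported size, and flanking insertion-repeat
#' description (`"61 -6 bp"` = 61 bp repeat with 6 mismatched
#' positions; `NA` = no repeat found). For repeat-flanked regions the
#' reported size refers to the sequence between the insertion repeats
#' and is therefore smaller than the coordinate span; BLi_Pp2 has no
#' repeats and its size is the span from the first to the last phage
#' gene.
#'
#' @return Data frame with columns `label`, `gc`, `size_bp`,
#'   `insertion_repeat`, `start`, `end`.
#' @export
dsm13_prophages <- function() {
  data.frame(
    label = paste0("BLi_Pp", 1:7),
    gc = c(38.10, 47.05, 42.50, 44.73, 39.89, 40.95, 35.58),
    size_bp = c(11177L, 27509L, 41566L, 38319L, 10524L, 44793L, 21733L),
    insertion_repeat = c("61 -6 bp", NA, "27 -1 bp", "256 -13 bp",
                         "50 -3 bp", "18 bp", "19 -1 bp"),
    start = c(927299L, 1317754L, 1422556L, 1504028L, 2855587L,
              3424376L, 4155490L),
    end = c(938595L, 1345262L, 1464174L, 1542847L, 2866209L,
            3469186L, 4177258L),
    stringsAsFactors = FALSE)
}

#' Signal-to-noise inputs from the DSM13 particle-DNA sequencing runs
#'
#' Average base coverage inside (signal) and outside (noise) the
#' prophage regions for the six published sequencing experiments:
#' wild type DSM13, lab strain MW3, the PBSX-deletion mutant, and
#' three replicates of the double mutant lacking both BLi_Pp2 (PBSX)
#' and BLi_Pp3. Feeding these into [signal_noise_stats()] reproduces
#' the published ratios and relative-noise percentages.
#'
#' @return Data frame with columns `dataset`, `signal`, `noise`.
#' @export
dsm13_coverage_summary <- function() {
  data.frame(
    dataset = c("DSM13", "MW3", "dPBSX", "dPBSX_dPp3_exp1",
                "dPBSX_dPp3_exp2", "dPBSX_dPp3_exp3"),
    signal = c(82.7, 187, 1447.2, 1671.8, 44.9, 664.6),
    noise = c(31.5, 79.7, 27.2, 68.3, 1.4, 5.4),
    stringsAsFactors = FALSE)
}

#' Read-mapping summary of the DSM13 particle-DNA sequencing runs
#'
#' Mapped and unmapped read counts per sequencing experiment.
#'
#' @return Data frame with columns `dataset`, `mapped`, `unmapped`.
#' @export
dsm13_read_counts <- function() {
  data.frame(
    dataset = c("DSM13", "MW3", "dPBSX", "dPBSX_dPp3_exp1",
                "dPBSX_dPp3_exp2", "dPBSX_dPp3_exp3"),
    mapped = c(1278534L, 3195030L, 3515890L, 5384670L, 194173L, 2030737L),
    unmapped = c(24221L, 41897L, 40356L, 1788078L, 94872L, 53687L),
    stringsAsFactors = FALSE)
}

#' DNase-treatment control primers
#'
#' The testA/testB primer pair amplifying a 159 bp control product from
#' DSM13 chromosomal DNA, used to verify complete nuclease removal of
#' free (non-particle-protected) DNA.
#'
#' @return List with elements `forward` and `reverse`.
#' @export
dsm13_control_primers <- function() {
  list(forward = "TCGATGTGTGACCGAGACGCGTAC",
       reverse = "CGAGTGACGACGAAGTTTCC")
}
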