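# hand-built six-subject table exercising every censoring rule
make_subjects <- function() {
  data.frame(
    subject_id = paste0("S", 1:6), family_id = rep(c("A", "B"), each = 3),
    carrier = c("carrier", "carrier", "noncarrier", "carrier", "carrier",
                "noncarrier"),
    gene = c("MLH1", "MLH1", "none", "MSH2", "MSH2", "none"),
    sex = rep(c("female", "male"), 3), country = "ANZ",
    height_m = c(1.7, 1.8, 1.6, 1.75, 1.65, 1.72),
    weight20_kg = c(65, 80, 55, NA, 60, 70),
    smoke20 = "never", alcohol20 = "ever",
    crc_age = c(44, NA, NA, 50, 44, NA),
    crc_verified = c("verified", NA, NA, "self_report", "verified", NA),
    tumour_site = c("right", NA, NA, "left", "rectum", NA),
    polypectomy_age = c(50, 40, NA, NA, NA, NA),
    other_cancer_age = NA_real_,
    death_age = NA_real_,
    last_contact_age = c(60, 55, 48, 62, 44, 39),
    is_proband = FALSE, stringsAsFactors = FALSE)
}
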