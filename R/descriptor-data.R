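# Constant tables behind the sequence descriptors.
#
# CTD three-group partitions of the 20 residues under 13 physicochemical
# attributes (seven hydrophobicity scales, normalized van der Waals volume,
# polarity, polarizability, charge, secondary-structure propensity, solvent
# accessibility), following the partitions in common use in protein feature
# toolkits. Each attribute's three groups are disjoint and cover all 20
# residues (asserted in the test suite).

CTD_GROUPS <- list(
  hydrophobicity_PRAM900101 = c("RKEDQN", "GASTPHY", "CLVIMFW"),
  hydrophobicity_ARGP820101 = c("QSTNGDE", "RAHCKMV", "LYPFIW"),
  hydrophobicity_ZIMJ680101 = c("QNGSWTDERA", "HMCKV", "LPFYI"),
  hydrophobicity_PONP930101 = c("KPDESNQT", "GRHA", "YMFWLCVI"),
  hydrophobicity_CASG920101 = c("KDEQPSRNTG", "AHYMLV", "FIWC"),
  hydrophobicity_ENGD860101 = c("RDKENQHYP", "SGTAW", "CVLIMF"),
  hydrophobicity_FASG890101 = c("KERSQD", "NTPG", "AYHWVMFLIC"),
  normwaalsvolume           = c("GASTPDC", "NVEQIL", "MHKFRYW"),
  polarity                  = c("LIFWCMVY", "PATGS", "HQRKNED"),
  polarizability            = c("GASDT", "CPNVEQIL", "KMHFRYW"),
  charge                    = c("KR", "ANCQGHILMFPSTWYV", "DE"),
  secondarystruct           = c("EALMQKRH", "VIYCWFT", "GNPSD"),
  solventaccess             = c("ALFCGIVW", "RKQEND", "MPSTHY")
)

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# sense-codon counts per residue in the standard genetic code (61 total)
CODON_COUNTS <- c(A = 4, C = 2, D = 2, E = 2, F = 2, G = 4, H = 2, I = 3,
                  K = 2, L = 6, M = 1, N = 2, P = 4, Q = 2, R = 6, S = 6,
                  T = 4, V = 4, W = 1, Y = 2)

# hydrophobicity (Tanford-style) and hydrophilicity (Hopp-Woods) values used
# by the amphiphilic pseudo-amino-acid correlation factors, standardized to
# zero mean and unit (population) variance over the 20 residues before use
APAAC_HYDROPHOBICITY <- c(A = 0.62, C = 0.29, D = -0.90, E = -0.74, F = 1.19,
                          G = 0.48, H = -0.40, I = 1.38, K = -1.50, L = 1.06,
                          M = 0.64, N = -0.78, P = 0.12, Q = -0.85, R = -2.53,
                          S = -0.18, T = -0.05, V = 1.08, W = 0.81, Y = 0.26)
APAAC_HYDROPHILICITY <- c(A = -0.5, C = -1.0, D = 3.0, E = 3.0, F = -2.5,
                          G = 0.0, H = -0.5, I = -1.8, K = 3.0, L = -1.8,
                          M = -1.3, N = 0.2, P = 0.0, Q = 0.2, R = 3.0,
                          S = 0.3, T = -0.4, V = -1.5, W = -3.4, Y = -2.3)

standardize_scale <- function(h) {
  h <- h[AA20]
  (h - mean(h)) / sqrt(mean((h - mean(h))^2))
}
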