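# Replication profile: C. militaris iPS1474 under light exposure.
#
# Runs the full pipeline on the publicly deposited iPS1474 genome-scale
# model of Cordyceps militaris (GitHub: sysbiomics/Cordyceps_militaris-tiGSMM)
# with the light-glucose (LG) / light-sucrose (LS) FPKM table and the
# light-vs-dark gene statistics of the accompanying transcriptome study.
# Those inputs are not redistributed here: download the model (.xml) and
# expression tables, convert the expression sheets to the TSV layouts
# described in ?read_fpkm and ?read_gene_stats, and point the paths below
# at them. Then:
#
#   Rscript -e 'tigsmm::run_pipeline("replication_profile.yaml")'
#
# Measured uptake rates (mmol/gDW/h) under light: glucose 0.1593,
# sucrose 0.0845. Threshold P50 over metabolic genes; growth pinned at
# the FBA maximum; active-reaction tolerance 1e-6; reporter significance
# at distinct-directional p < 0.05.

model_path: PATH/TO/iPS1474.xml
model_dialect: sbml_fbc
fpkm_path: PATH/TO/fpkm_light.tsv          # columns: gene_id, LG, LS
gene_stats_path: PATH/TO/light_dark_de.tsv # columns: gene_id, p_value, direction
conditions: [LG, LS]
carbon:
  LG: {exchange: EX_glc, rate: 0.1593}
  LS: {exchange: EX_sucr, rate: 0.0845}
open_nutrients: [EX_nh4, EX_pi, EX_so4, EX_h2o, EX_h]
percentile: 50
growth_fraction: 1.0
zero_tolerance: 1.0e-6
alpha: 0.05
seed: 1
output_dir: replication_out
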