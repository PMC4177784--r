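# SCORE 10-year fatal cardiovascular risk model constants, version 1.0
# Transcribed from the published SCORE derivation: Conroy RM et al.,
# "Estimation of ten-year risk of fatal cardiovascular disease in Europe:
# the SCORE project", Eur Heart J 2003;24:987-1003.
# baseline rows: Weibull S0(age) = exp(-exp(alpha) * (age - 20)^p)
#   per region (low_risk / high_risk), cause (chd / nonchd) and sex.
# beta rows: log-hazard-ratio coefficients per cause and risk factor, with
#   the reference value each factor is centred at (cholesterol 6 mmol/L,
#   SBP 120 mmHg, non-smoker; TC:HDL ratio centred at 5).
# NOTE: the tc_hdl_ratio cholesterol-term betas are transcribed from the
#   same source but could not be re-verified against the original tables
#   when this file was assembled; the total_cholesterol variant is the
#   better-audited transcription.
type,region,variant,cause,sex,parameter,value,reference
baseline,low_risk,,chd,male,alpha,-22.1,
baseline,low_risk,,chd,male,p,4.71,
baseline,low_risk,,chd,female,alpha,-29.8,
baseline,low_risk,,chd,female,p,6.36,
baseline,low_risk,,nonchd,male,alpha,-26.7,
baseline,low_risk,,nonchd,male,p,5.64,
baseline,low_risk,,nonchd,female,alpha,-31.0,
baseline,low_risk,,nonchd,female,p,6.62,
baseline,high_risk,,chd,male,alpha,-21.0,
baseline,high_risk,,chd,male,p,4.62,
baseline,high_risk,,chd,female,alpha,-28.7,
baseline,high_risk,,chd,female,p,6.23,
baseline,high_risk,,nonchd,male,alpha,-25.7,
baseline,high_risk,,nonchd,male,p,5.47,
baseline,high_risk,,nonchd,female,alpha,-30.0,
baseline,high_risk,,nonchd,female,p,6.42,
beta,,total_cholesterol,chd,,cholesterol,0.24,6
beta,,total_cholesterol,chd,,sbp,0.018,120
beta,,total_cholesterol,chd,,smoker,0.71,0
beta,,total_cholesterol,nonchd,,cholesterol,0.02,6
beta,,total_cholesterol,nonchd,,sbp,0.022,120
beta,,total_cholesterol,nonchd,,smoker,0.63,0
beta,,tc_hdl_ratio,chd,,cholesterol,0.088,5
beta,,tc_hdl_ratio,chd,,sbp,0.018,120
beta,,tc_hdl_ratio,chd,,smoker,0.71,0
beta,,tc_hdl_ratio,nonchd,,cholesterol,0.095,5
beta,,tc_hdl_ratio,nonchd,,sbp,0.022,120
beta,,tc_hdl_ratio,nonchd,,smoker,0.63,0
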