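child_code,parent_code
HLGT_NEPHROPATHIES,SOC_RENAL
HLT_GN_NS,HLGT_NEPHROPATHIES
HLT_NEPHRITIS,SOC_RENAL
HLT_NEPHROPATHY,SOC_RENAL
HLT_RENAL_DIS,SOC_RENAL
HLT_RENAL_FAIL,SOC_RENAL
HLT_RENAL_HTN,SOC_RENAL
HLT_RENAL_VASC,SOC_RENAL
HLT_UTI,SOC_RENAL
HLT_OEDEMA,SOC_GEN
HLT_GI_SIGNS,SOC_GI
HLT_GI_MOT,SOC_GI
HLT_HEAD,SOC_NERV
HLT_FATIGUE,SOC_GEN
HLT_RASH,SOC_SKIN
HLT_EMB,SOC_VASC
PT_TIN,HLT_NEPHRITIS
PT_AKI,HLT_RENAL_FAIL
PT_CKD,HLT_RENAL_FAIL
PT_OLIGURIA,HLT_RENAL_FAIL
PT_RENAL_FAILURE,HLT_RENAL_FAIL
PT_RENAL_IMPAIRMENT,HLT_RENAL_FAIL
PT_FLUID_RETENTION,HLT_OEDEMA
PT_RENAL_DISORDER,HLT_RENAL_DIS
PT_NEPHROPATHY,HLT_NEPHROPATHY
PT_NEPHROPATHY,HLT_RENAL_DIS
PT_TOXIC_NEPHROPATHY,HLT_NEPHROPATHY
PT_NEPHROTIC_SYNDROME,HLT_GN_NS
PT_RAS,HLT_RENAL_VASC
PT_TMA,HLT_RENAL_VASC
PT_TMA,HLT_EMB
PT_RENAL_HTN,HLT_RENAL_HTN
PT_NAUSEA,HLT_GI_SIGNS
PT_VOMITING,HLT_GI_SIGNS
PT_DIARRHOEA,HLT_GI_MOT
PT_HEADACHE,HLT_HEAD
PT_FATIGUE,HLT_FATIGUE
PT_RASH,HLT_RASH
PT_OEDEMA_PERIPH,HLT_OEDEMA
PT_CYSTITIS,HLT_UTI
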