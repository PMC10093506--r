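code,name,level
SOC_RENAL,Renal and urinary disorders,SOC
SOC_GI,Gastrointestinal disorders,SOC
SOC_GEN,General disorders and administration site conditions,SOC
SOC_NERV,Nervous system disorders,SOC
SOC_SKIN,Skin and subcutaneous tissue disorders,SOC
SOC_VASC,Vascular disorders,SOC
HLGT_NEPHROPATHIES,Nephropathies,HLGT
HLT_GN_NS,Glomerulonephritis and nephrotic syndrome,HLT
HLT_NEPHRITIS,Nephritis NEC,HLT
HLT_NEPHROPATHY,Nephropathies and tubular disorders NEC,HLT
HLT_RENAL_DIS,Renal disorders NEC,HLT
HLT_RENAL_FAIL,Renal failure and impairment,HLT
HLT_RENAL_HTN,Renal hypertension and related conditions,HLT
HLT_RENAL_VASC,Renal vascular and ischaemic conditions,HLT
HLT_UTI,Urinary tract infections,HLT
HLT_OEDEMA,Oedema NEC,HLT
HLT_GI_SIGNS,Nausea and vomiting symptoms,HLT
HLT_GI_MOT,Diarrhoea symptoms,HLT
HLT_HEAD,Headaches NEC,HLT
HLT_FATIGUE,Asthenic conditions,HLT
HLT_RASH,"Rashes, eruptions and exanthems NEC",HLT
HLT_EMB,Embolism and thrombosis,HLT
PT_TIN,Tubulointerstitial nephritis,PT
PT_AKI,Acute kidney injury,PT
PT_CKD,Chronic kidney disease,PT
PT_OLIGURIA,Oliguria,PT
PT_RENAL_FAILURE,Renal failure,PT
PT_RENAL_IMPAIRMENT,Renal impairment,PT
PT_FLUID_RETENTION,Fluid retention,PT
PT_RENAL_DISORDER,Renal disorder,PT
PT_NEPHROPATHY,Nephropathy,PT
PT_TOXIC_NEPHROPATHY,Toxic nephropathy,PT
PT_NEPHROTIC_SYNDROME,Nephrotic syndrome,PT
PT_RAS,Renal artery stenosis,PT
PT_TMA,Thrombotic microangiopathy,PT
PT_RENAL_HTN,Renal hypertension,PT
PT_NAUSEA,Nausea,PT
PT_VOMITING,Vomiting,PT
PT_DIARRHOEA,Diarrhoea,PT
PT_HEADACHE,Headache,PT
PT_FATIGUE,Fatigue,PT
PT_RASH,Rash,PT
PT_OEDEMA_PERIPH,Oedema peripheral,PT
PT_CYSTITIS,Cystitis,PT
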