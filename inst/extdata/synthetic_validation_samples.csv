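sample_id,group,cohort
V_B01,benign,validation
V_B02,benign,validation
V_B03,benign,validation
V_B04,benign,validation
V_B05,benign,validation
V_B06,benign,validation
V_B07,benign,validation
V_B08,benign,validation
V_B09,benign,validation
V_B10,benign,validation
V_B11,benign,validation
V_B12,benign,validation
V_B13,benign,validation
V_B14,benign,validation
V_B15,benign,validation
V_B16,benign,validation
V_B17,benign,validation
V_B18,benign,validation
V_M01,malignant,validation
V_M02,malignant,validation
V_M03,malignant,validation
V_M04,malignant,validation
V_M05,malignant,validation
V_M06,malignant,validation
V_M07,malignant,validation
V_M08,malignant,validation
V_M09,malignant,validation
V_M10,malignant,validation
V_M11,malignant,validation
V_M12,malignant,validation
V_M13,malignant,validation
V_M14,malignant,validation
V_M15,malignant,validation
V_M16,malignant,validation
V_M17,malignant,validation
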