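table,column,type,description
dispensing,patient_id,character,Opaque patient identifier linking all tables
dispensing,dispense_date,date ISO-8601,Date the prescription was dispensed
dispensing,drug_name,character,Drug identifier (controlled vocabulary)
dispensing,drug_class,character,"One of DOAC_dabigatran, DOAC_rivaroxaban, DOAC_apixaban, VKA, antiplatelet, aspirin, NSAID, other"
dispensing,quantity,numeric,Dose units dispensed (positive)
dispensing,daily_dose_units,numeric,Prescriber instruction in units/day; empty when missing
hospital,patient_id,character,Patient identifier
hospital,admission_date,date ISO-8601,Episode admission date
hospital,discharge_date,date ISO-8601,Episode discharge date (>= admission)
hospital,position,integer,Diagnostic position (1 = main condition)
hospital,diagnosis_code,character,ICD-10 code (dots optional)
demographics,patient_id,character,Patient identifier
demographics,sex,character,female or male
demographics,birth_date,date ISO-8601,Date of birth
demographics,exit_date,date ISO-8601,Death or deregistration date; empty when still registered
demographics,exit_reason,character,"death, deregistered, or none"
latent_truth,patient_id,character,Patient identifier (simulator output only; never read by the pipeline)
latent_truth,index_date,date ISO-8601,True first DOAC dispensing date
latent_truth,index_drug,character,True first DOAC
latent_truth,true_discontinuation_day,numeric,Latent discontinuation day offset from index (may exceed the observation window; the patient then persists); empty when never discontinuing
latent_truth,true_pathway,character,"persist, cease, reinitiate, or switch_vka"
latent_truth,true_adherence_level,numeric,Realised supply-to-exposure ratio
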