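"domain_key","sdtm_code","display_name","custom","keywords"
"medical_history","MH","Medical History",FALSE,"medical history"
"adverse_event","AE","Adverse Event",FALSE,"adverse event;sae"
"laboratory","LB","Laboratory test results",FALSE,"laborator;coagulation;hematology;chemistry;urinalysis;panel"
"disposition","DS","Disposition",FALSE,"disposition;study completion;end of study"
"vital_signs","VS","Vital Signs",FALSE,"vital sign"
"concomitant_medications","CM","Concomitant Medications",FALSE,"concomitant;medication"
"questionnaire","QS","Questionnaire/Patient reported outcome",FALSE,"questionnaire;patient reported outcome;quality of life"
"demographics","DM","Demographics",FALSE,"demograph"
"ecg","EG","ECG",FALSE,"ecg;electrocardiogram"
"disease_characteristics","ZC","Disease Characteristics",TRUE,"disease characteristic"
"substance_use","SU","Substance Use",FALSE,"substance use;tobacco;alcohol;smoking"
"surgery","","Surgery",FALSE,"surgery;surgical;procedures"
"physical_exam","PE","Physical Examination",FALSE,"physical exam"
"tumor_response","RS","Tumor response",FALSE,"tumor response;recist"
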