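# Default Triple Whammy drug definition lists (generic names).
# Matching is exact after normalization (trim / case-fold / width-unify);
# extend these lists with brand names for a real JADER release.
rasi:
  - enalapril
  - lisinopril
  - captopril
  - imidapril
  - temocapril
  - perindopril
  - trandolapril
  - benazepril
  - candesartan
  - losartan
  - valsartan
  - telmisartan
  - olmesartan
  - irbesartan
  - azilsartan
  - aliskiren
diuretic:
  - furosemide
  - torasemide
  - azosemide
  - bumetanide
  - trichlormethiazide
  - hydrochlorothiazide
  - benzylhydrochlorothiazide
  - indapamide
  - tripamide
  - mefruside
  - spironolactone
  - eplerenone
  - potassium canrenoate
  - triamterene
  - tolvaptan
nsaid:
  - loxoprofen
  - diclofenac
  - ibuprofen
  - naproxen
  - celecoxib
  - etodolac
  - meloxicam
  - indomethacin
  - ketoprofen
  - flurbiprofen
  - aceclofenac
  - sulindac
  - piroxicam
  - lornoxicam
  - mefenamic acid
  - zaltoprofen
  - nabumetone
  - pranoprofen
  - tiaprofenic acid
  - oxaprozin
aspirin_names:
  - aspirin
  - acetylsalicylic acid
  - aspirin dialuminate
aki_risk:
  - valaciclovir hydrochloride
  - valaciclovir
  - eldecalcitol
  - edaravone
  - aciclovir
  - tazobactam-piperacillin hydrate
  - tazobactam-piperacillin
  - vancomycin hydrochloride
  - vancomycin
  - famotidine
  - levofloxacin
  - esomeprazole
  - lansoprazole
  - omeprazole
  - pantoprazole
  - rabeprazole
  - vonoprazan
  - amikacin
  - arbekacin
  - bekanamycin
  - dibekacin
  - fradiomycin
  - gentamicin
  - isepamicin
  - kanamycin
  - micronomicin
  - netilmicin
  - paromomycin
  - ribostamycin
  - streptomycin
  - tobramycin
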