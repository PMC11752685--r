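# Built-in library of drug-like structures used by the synthetic-data
# generators. Keeping real, chemically valid SMILES embedded in the package
# guarantees that every fixture is parseable and featurizable offline.

#' Built-in drug-like SMILES library
#'
#' Returns the package's embedded list of drug-like molecules (common small
#' -molecule drugs spanning a broad range of size, lipophilicity and polarity)
#' used by [generate_compound_table()] and [generate_ic50_training_set()].
#' All entries parse with the package featurizer.
#'
#' @return Named character vector of SMILES strings; names are compound names.
#' @export
drug_smiles_library <- function() {
  c(
    aspirin = "CC(=O)Oc1ccccc1C(=O)O",
    paracetamol = "CC(=O)Nc1ccc(O)cc1",
    ibuprofen = "CC(C)Cc1ccc(cc1)C(C)C(=O)O",
    naproxen = "COc1ccc2cc(ccc2c1)C(C)C(=O)O",
    diclofenac = "OC(=O)Cc1ccccc1Nc1c(Cl)cccc1Cl",
    indomethacin = "COc1ccc2c(c1)c(CC(=O)O)c(C)n2C(=O)c1ccc(Cl)cc1",
    ketoprofen = "CC(C(=O)O)c1cccc(c1)C(=O)c1ccccc1",
    celecoxib = "Cc1ccc(cc1)-c1cc(nn1-c1ccc(cc1)S(N)(=O)=O)C(F)(F)F",
    caffeine = "Cn1cnc2c1c(=O)n(C)c(=O)n2C",
    theophylline = "Cn1c2[nH]cnc2c(=O)n(C)c1=O",
    warfarin = "CC(=O)CC(c1ccccc1)c1c(O)c2ccccc2oc1=O",
    phenytoin = "O=C1NC(=O)C(N1)(c1ccccc1)c1ccccc1",
    carbamazepine = "NC(=O)N1c2ccccc2C=Cc2ccccc21",
    valproate = "CCCC(CCC)C(=O)O",
    lamotrigine = "Nc1nnc(c(N)n1)-c1cccc(Cl)c1Cl",
    gabapentin = "NCC1(CC(=O)O)CCCCC1",
    diazepam = "CN1c2ccc(Cl)cc2C(=NCC1=O)c1ccccc1",
    lorazepam = "OC1N=C(c2ccccc2Cl)c2cc(Cl)ccc2NC1=O",
    alprazolam = "Cc1nnc2n1-c1ccc(Cl)cc1C(=NC2)c1ccccc1",
    midazolam = "Cc1ncc2n1-c1ccc(Cl)cc1C(=NC2)c1ccccc1F",
    zolpidem = "Cc1ccc(cn1)-c1c(CC(=O)N(C)C)n2ccc(C)cc2n1",
    haloperidol = "OC1(CCN(CCCC(=O)c2ccc(F)cc2)CC1)c1ccc(Cl)cc1",
    risperidone = "Cc1nc2CCCCn2c(=O)c1CCN1CCC(CC1)c1noc2cc(F)ccc12",
    olanzapine = "Cc1cc2c(s1)Nc1ccccc1N=C2N1CCN(C)CC1",
    quetiapine = "OCCOCCN1CCN(CC1)C1=Nc2ccccc2Sc2ccccc12",
    clozapine = "CN1CCN(CC1)C1=Nc2cc(Cl)ccc2Nc2ccccc12",
    chlorpromazine = "CN(C)CCCN1c2ccccc2Sc2ccc(Cl)cc21",
    fluoxetine = "CNCCC(Oc1ccc(cc1)C(F)(F)F)c1ccccc1",
    sertraline = "CNC1CCC(c2ccc(Cl)c(Cl)c2)c2ccccc12",
    paroxetine = "Fc1ccc(cc1)C1CCNCC1COc1ccc2OCOc2c1",
    citalopram = "CN(C)CCCC1(OCc2cc(ccc21)C#N)c1ccc(F)cc1",
    venlafaxine = "CN(C)CC(c1ccc(OC)cc1)C1(O)CCCCC1",
    duloxetine = "CNCCC(Oc1cccc2ccccc12)c1cccs1",
    bupropion = "CC(NC(C)(C)C)C(=O)c1cccc(Cl)c1",
    amitriptyline = "CN(C)CCC=C1c2ccccc2CCc2ccccc21",
    imipramine = "CN(C)CCCN1c2ccccc2CCc2ccccc21",
    mirtazapine = "CN1CCN2c3ccccc3Cc3cccnc3C2C1",
    trazodone = "O=c1n(CCCN2CCN(CC2)c2cccc(Cl)c2)nc2ccccn12",
    morphine = "CN1CCC23c4c5ccc(O)c4OC2C(O)C=CC3C1C5",
    codeine = "CN1CCC23c4c5ccc(OC)c4OC2C(O)C=CC3C1C5",
    fentanyl = "CCC(=O)N(c1ccccc1)C1CCN(CCc2ccccc2)CC1",
    methadone = "CCC(=O)C(CC(C)N(C)C)(c1ccccc1)c1ccccc1",
    tramadol = "CN(C)CC1CCCCC1(O)c1cccc(OC)c1",
    naloxone = "OC1(CC=C)N2CCC34c5ccc(O)c(OC3C1=O)c5CC2C4",
    atenolol = "CC(C)NCC(O)COc1ccc(CC(N)=O)cc1",
    metoprolol = "COCCc1ccc(OCC(O)CNC(C)C)cc1",
    propranolol = "CC(C)NCC(O)COc1cccc2ccccc12",
    carvedilol = "COc1ccccc1OCCNCC(O)COc1cccc2[nH]c3ccccc3c12",
    labetalol = "CC(Cc1ccccc1)NCC(O)c1ccc(O)c(C(N)=O)c1",
    amlodipine = "CCOC(=O)C1=C(COCCN)NC(C)=C(C1c1ccccc1Cl)C(=O)OC",
    nifedipine = "COC(=O)C1=C(C)NC(C)=C(C(=O)OC)C1c1ccccc1[N+](=O)[O-]",
    verapamil = "COc1ccc(CCN(C)CCCC(C#N)(C(C)C)c2ccc(OC)c(OC)c2)cc1OC",
    diltiazem = "CN(C)CCN1c2ccccc2SC(c2ccc(OC)cc2)C(OC(C)=O)C1=O",
    lisinopril = "NCCCCC(NC(CCc1ccccc1)C(=O)O)C(=O)N1CCCC1C(=O)O",
    enalapril = "CCOC(=O)C(CCc1ccccc1)NC(C)C(=O)N1CCCC1C(=O)O",
    captopril = "CC(CS)C(=O)N1CCCC1C(=O)O",
    losartan = "CCCCc1nc(Cl)c(CO)n1Cc1ccc(cc1)-c1ccccc1-c1nnn[nH]1",
    valsartan = "CCCCC(=O)N(Cc1ccc(cc1)-c1ccccc1-c1nnn[nH]1)C(C(C)C)C(=O)O",
    irbesartan = "CCCCC1=NC2(CCCC2)C(=O)N1Cc1ccc(cc1)-c1ccccc1-c1nnn[nH]1",
    hydrochlorothiazide = "NS(=O)(=O)c1cc2c(cc1Cl)NCNS2(=O)=O",
    furosemide = "NS(=O)(=O)c1cc(C(=O)O)c(NCc2ccco2)cc1Cl",
    spironolactone = "CC(=O)SC1CCC2(C)C(CCC3(C)C2CCC23CCC(=O)O2)C1",
    digoxin = "CC1OC(CC(O)C1O)OC1CC(O)C(C)OC1OC1CC(O)C(C)OC1OC1CCC2(C)C(CCC3C2CCC2(C)C(CCC32O)C2=CC(=O)OC2)C1",
    atorvastatin = "CC(C)c1c(C(=O)Nc2ccccc2)c(-c2ccccc2)c(-c2ccc(F)cc2)n1CCC(O)CC(O)CC(=O)O",
    simvastatin = "CCC(C)(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12",
    lovastatin = "CCC(C)C(=O)OC1CC(C)C=C2C=CC(C)C(CCC3CC(O)CC(=O)O3)C12",
    pravastatin = "CCC(C)C(=O)OC1CC(O)C=C2C=CC(C)C(CCC(O)CC(O)CC(=O)O)C12",
    rosuvastatin = "CC(C)c1nc(N(C)S(C)(=O)=O)nc(-c2ccc(F)cc2)c1C=CC(O)CC(O)CC(=O)O",
    fenofibrate = "CC(C)OC(=O)C(C)(C)Oc1ccc(cc1)C(=O)c1ccc(Cl)cc1",
    gemfibrozil = "Cc1ccc(C)c(OCCCC(C)(C)C(=O)O)c1",
    ezetimibe = "OC(CCC1C(N(C1=O)c1ccc(F)cc1)c1ccc(O)cc1)c1ccc(F)cc1",
    metformin = "CN(C)C(=N)NC(N)=N",
    glibenclamide = "COc1ccc(Cl)cc1C(=O)NCCc1ccc(cc1)S(=O)(=O)NC(=O)NC1CCCCC1",
    glipizide = "Cc1cnc(cn1)C(=O)NCCc1ccc(cc1)S(=O)(=O)NC(=O)NC1CCCCC1",
    pioglitazone = "CCc1ccc(CCOc2ccc(CC3SC(=O)NC3=O)cc2)nc1",
    rosiglitazone = "CN(CCOc1ccc(CC2SC(=O)NC2=O)cc1)c1ccccn1",
    sitagliptin = "NC(CC(=O)N1CCn2c(C1)nnc2C(F)(F)F)Cc1cc(F)c(F)cc1F",
    omeprazole = "COc1ccc2[nH]c(nc2c1)S(=O)Cc1ncc(C)c(OC)c1C",
    lansoprazole = "Cc1c(OCC(F)(F)F)ccnc1CS(=O)c1nc2ccccc2[nH]1",
    pantoprazole = "COc1ccnc(CS(=O)c2nc3cc(OC(F)F)ccc3[nH]2)c1OC",
    ranitidine = "CNC(=C[N+](=O)[O-])NCCSCc1ccc(CN(C)C)o1",
    cimetidine = "CNC(=NC#N)NCCSCc1nc[nH]c1C",
    famotidine = "NC(N)=Nc1nc(CSCCC(N)=NS(N)(=O)=O)cs1",
    ondansetron = "Cc1nccn1CC1CCc2c(C1=O)c1ccccc1n2C",
    metoclopramide = "CCN(CC)CCNC(=O)c1cc(Cl)c(N)cc1OC",
    domperidone = "O=c1[nH]c2ccccc2n1CCCN1CCC(CC1)n1c(=O)[nH]c2cc(Cl)ccc21",
    loperamide = "CN(C)C(=O)C(CCN1CCC(O)(CC1)c1ccc(Cl)cc1)(c1ccccc1)c1ccccc1",
    amoxicillin = "CC1(C)SC2C(NC(=O)C(N)c3ccc(O)cc3)C(=O)N2C1C(=O)O",
    ampicillin = "CC1(C)SC2C(NC(=O)C(N)c3ccccc3)C(=O)N2C1C(=O)O",
    cephalexin = "CC1=C(N2C(SC1)C(NC(=O)C(N)c1ccccc1)C2=O)C(=O)O",
    ciprofloxacin = "OC(=O)c1cn(C2CC2)c2cc(N3CCNCC3)c(F)cc2c1=O",
    levofloxacin = "CC1COc2c(N3CCN(C)CC3)c(F)cc3c(=O)c(cn1c23)C(=O)O",
    moxifloxacin = "COc1c(N2CC3CCCNC3C2)c(F)cc2c(=O)c(cn(C3CC3)c12)C(=O)O",
    azithromycin = "CCC1OC(=O)C(C)C(OC2CC(C)(OC)C(O)C(C)O2)C(C)C(OC2OC(C)CC(C2O)N(C)C)C(C)(O)CC(C)CN(C)C(C)C(O)C1(C)O",
    erythromycin = "CCC1OC(=O)C(C)C(OC2CC(C)(OC)C(O)C(C)O2)C(C)C(OC2OC(C)CC(C2O)N(C)C)C(C)(O)CC(C)C(=O)C(C)C(O)C1(C)O",
    clarithromycin = "CCC1OC(=O)C(C)C(OC2CC(C)(OC)C(O)C(C)O2)C(C)C(OC2OC(C)CC(C2O)N(C)C)C(C)(OC)CC(C)C(=O)C(C)C(O)C1(C)O",
    doxycycline = "CC1c2cccc(O)c2C(=O)C2=C(O)C3(O)C(=O)C(C(N)=O)=C(O)C(N(C)C)C3C(O)C12",
    tetracycline = "CC1(O)c2cccc(O)c2C(=O)C2=C(O)C3(O)C(=O)C(C(N)=O)=C(O)C(N(C)C)C3CC12",
    trimethoprim = "COc1cc(Cc2cnc(N)nc2N)cc(OC)c1OC",
    sulfamethoxazole = "Cc1cc(NS(=O)(=O)c2ccc(N)cc2)no1",
    metronidazole = "Cc1ncc(n1CCO)[N+](=O)[O-]",
    rifampicin = "COC1C=COC2(C)Oc3c(C)c(O)c4c(O)c(NC(=O)C(C)=CC=CC(C)C(O)C(C)C(O)C(C)C(OC(C)=O)C1C)c(C=NN1CCN(C)CC1)c(O)c4c3C2=O",
    isoniazid = "NNC(=O)c1ccncc1",
    pyrazinamide = "NC(=O)c1cnccn1",
    ethambutol = "CCC(CO)NCCNC(CC)CO",
    fluconazole = "OC(Cn1cncn1)(Cn1cncn1)c1ccc(F)cc1F",
    itraconazole = "CCC(C)n1ncn(c1=O)-c1ccc(cc1)N1CCN(CC1)c1ccc(OCC2COC(Cn3cncn3)(O2)c2ccc(Cl)cc2Cl)cc1",
    ketoconazole = "CC(=O)N1CCN(CC1)c1ccc(OCC2COC(Cn3ccnc3)(O2)c2ccc(Cl)cc2Cl)cc1",
    voriconazole = "CC(c1ncncc1F)C(O)(Cn1cncn1)c1ccc(F)cc1F",
    terbinafine = "CC(C)(C)C#CC=CCN(C)Cc1cccc2ccccc12",
    acyclovir = "Nc1nc2n(COCCO)cnc2c(=O)[nH]1",
    zidovudine = "Cc1cn(C2CC(N=[N+]=[N-])C(CO)O2)c(=O)[nH]c1=O",
    lamivudine = "Nc1ccn(C2CSC(CO)O2)c(=O)n1",
    oseltamivir = "CCOC(=O)C1=CC(OC(CC)CC)C(NC(C)=O)C(N)C1",
    ribavirin = "NC(=O)c1ncn(n1)C1OC(CO)C(O)C1O",
    chloroquine = "CCN(CC)CCCC(C)Nc1ccnc2cc(Cl)ccc12",
    hydroxychloroquine = "CCN(CCO)CCCC(C)Nc1ccnc2cc(Cl)ccc12",
    quinine = "COc1ccc2nccc(C(O)C3CC4CCN3CC4C=C)c2c1",
    mefloquine = "OC(C1CCCCN1)c1cc(nc2c(cccc12)C(F)(F)F)C(F)(F)F",
    artemisinin = "CC1CCC2C(C)C(=O)OC3OC4(C)CCC1C23OO4",
    praziquantel = "O=C1N2CC3c4ccccc4CCN3C(=O)C2CCC1",
    albendazole = "CCCSc1ccc2[nH]c(NC(=O)OC)nc2c1",
    mebendazole = "COC(=O)Nc1nc2cc(ccc2[nH]1)C(=O)c1ccccc1",
    ivermectin = "CCC(C)C1OC2(CC3CC(CC=C(C)C(OC4CC(OC)C(OC5CC(OC)C(O)C(C)O5)C(C)O4)C(C)C=CC=C4COC5C(O)C(C)=CC(C(=O)O3)C45O)O2)C=CC1C",
    prednisone = "CC12CC(=O)C3C(CCC4=CC(=O)C=CC34C)C1CCC2(O)C(=O)CO",
    prednisolone = "CC12CC(O)C3C(CCC4=CC(=O)C=CC34C)C1CCC2(O)C(=O)CO",
    dexamethasone = "CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)CO",
    hydrocortisone = "CC12CC(O)C3C(CCC4=CC(=O)CCC34C)C1CCC2(O)C(=O)CO",
    budesonide = "CCCC1OC2CC3C4CCC5=CC(=O)C=CC5(C)C4C(O)CC3(C)C2(O1)C(=O)CO",
    fluticasone = "CC1CC2C3CC(F)C4=CC(=O)C=CC4(C)C3(F)C(O)CC2(C)C1(O)C(=O)SCF",
    beclometasone = "CC1CC2C3CCC4=CC(=O)C=CC4(C)C3(Cl)C(O)CC2(C)C1(O)C(=O)CO",
    estradiol = "CC12CCC3c4ccc(O)cc4CCC3C1CCC2O",
    testosterone = "CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
    progesterone = "CC(=O)C1CCC2C3CCC4=CC(=O)CCC4(C)C3CCC12C",
    tamoxifen = "CCC(=C(c1ccccc1)c1ccc(OCCN(C)C)cc1)c1ccccc1",
    raloxifene = "OC1=CC=C2C=C(SC2=C1)C(=O)c1ccc(OCCN2CCCCC2)cc1",
    levothyroxine = "NC(Cc1cc(I)c(Oc2cc(I)c(O)c(I)c2)c(I)c1)C(=O)O",
    methotrexate = "CN(Cc1cnc2nc(N)nc(N)c2n1)c1ccc(cc1)C(=O)NC(CCC(=O)O)C(=O)O",
    cyclophosphamide = "ClCCN(CCCl)P1(=O)NCCCO1",
    tamsulosin = "CCOc1ccccc1OCCNC(C)Cc1ccc(OC)c(c1)S(N)(=O)=O",
    sildenafil = "CCCc1nn(C)c2c1nc([nH]c2=O)-c1cc(ccc1OCC)S(=O)(=O)N1CCN(C)CC1",
    tadalafil = "CN1CC(=O)N2C(C1=O)Cc1c([nH]c3ccccc13)C2c1ccc2OCOc2c1",
    finasteride = "CC(C)(C)NC(=O)C1CCC2C3CCC4=CC(=O)NC4(C)C3CCC12C",
    allopurinol = "O=c1[nH]cnc2[nH]ncc12",
    colchicine = "COC(=O)C1=CC2=CC=C(OC)C(=O)C=C2c2cc(OC)c(OC)c(OC)c2CC1NC(C)=O",
    probenecid = "CCCN(CCC)S(=O)(=O)c1ccc(cc1)C(=O)O",
    montelukast = "CC(C)(O)c1ccccc1CCC(SCC1(CC(=O)O)CC1)c1cccc(C=Cc2ccc3ccc(Cl)cc3n2)c1",
    zafirlukast = "COc1cc(ccc1Cc1cn(C)c2ccc(NC(=O)OC3CCCC3)cc12)C(=O)Nc1ccccc1S(C)(=O)=O",
    salbutamol = "CC(C)(C)NCC(O)c1ccc(O)c(CO)c1",
    salmeterol = "OCc1cc(ccc1O)C(O)CNCCCCCCOCCCCc1ccccc1",
    terbutaline = "CC(C)(C)NCC(O)c1cc(O)cc(O)c1",
    ipratropium = "CC(C)[N+]1(C)C2CCC1CC(C2)OC(=O)C(CO)c1ccccc1",
    theobromine = "Cn1cnc2c1c(=O)[nH]c(=O)n2C",
    loratadine = "CCOC(=O)N1CCC(CC1)=C1c2ccc(Cl)cc2CCc2cccnc21",
    cetirizine = "OC(=O)COCCN1CCN(CC1)C(c1ccccc1)c1ccc(Cl)cc1",
    fexofenadine = "CC(C)(C(=O)O)c1ccc(cc1)C(O)CCCN1CCC(CC1)C(O)(c1ccccc1)c1ccccc1",
    diphenhydramine = "CN(C)CCOC(c1ccccc1)c1ccccc1",
    chlorpheniramine = "CN(C)CCC(c1ccc(Cl)cc1)c1ccccn1",
    promethazine = "CC(CN1c2ccccc2Sc2ccccc21)N(C)C",
    ketotifen = "CN1CCC(CC1)=C1c2ccccc2CC(=O)c2sccc21",
    cromolyn = "OC(COc1cccc2c(=O)cc(oc12)C(=O)O)COc1cccc2c(=O)cc(oc12)C(=O)O",
    sumatriptan = "CNS(=O)(=O)Cc1ccc2[nH]cc(CCN(C)C)c2c1",
    rizatriptan = "CN(C)CCc1c[nH]c2ccc(Cn3cncn3)cc12",
    ergotamine = "CC1(NC(=O)C2CC3c4cccc5[nH]cc(CC3N(C)C2)c45)OC2(O)C3CCCN3C(=O)C(Cc3ccccc3)N2C1=O",
    dihydroergotamine = "CC1(NC(=O)C2CC3C(Cc4c[nH]c5cccc3c45)N(C)C2)OC2(O)C3CCCN3C(=O)C(Cc3ccccc3)N2C1=O",
    ropinirole = "CCCN(CCC)CCc1cccc2NC(=O)Cc12",
    pramipexole = "CCCNC1CCc2nc(N)sc2C1",
    levodopa = "NC(Cc1ccc(O)c(O)c1)C(=O)O",
    selegiline = "CC(Cc1ccccc1)N(C)CC#C",
    entacapone = "CCN(CC)C(=O)C(=CC1=CC(O)=C(O)C=C1[N+](=O)[O-])C#N",
    donepezil = "COc1cc2CC(CC3CCN(Cc4ccccc4)CC3)C(=O)c2cc1OC",
    rivastigmine = "CCN(C)C(=O)Oc1cccc(c1)C(C)N(C)C",
    memantine = "CC12CC3CC(C)(C1)CC(N)(C3)C2",
    baclofen = "NCC(CC(=O)O)c1ccc(Cl)cc1",
    tizanidine = "Clc1ccc2nsnc2c1NC1=NCCN1",
    dantrolene = "O=C1CN(N=Cc2ccc(o2)-c2ccc(cc2)[N+](=O)[O-])C(=O)N1",
    tacrolimus = "CC1CC(OC)C2OC(=O)C3CCCCN3C(=O)C(=O)C2(O)OC(C(CC(C)CC(OC)c2ccc(O)c(OC)c2)C(C)CC1=O)C(C)C1CCC(O)C(OC)C1",
    sirolimus = "CC1CCC2CC(OC)C(=CC=CC=CC(C)CC(C)C(=O)C(OC)C(O)C(C)=CC(C)C(=O)CC(OC(=O)C3CCCCN3C(=O)C(=O)C1(O)O2)C(C)CC1CCC(O)C(OC)C1)C",
    mycophenolate = "COc1c(C)c2COC(=O)c2c(O)c1CC=C(C)CCC(=O)O",
    azathioprine = "Cn1cnc(c1Sc1ncnc2[nH]cnc12)[N+](=O)[O-]",
    leflunomide = "Cc1ccc(NC(=O)c2cc(C)on2)cc1C(F)(F)F",
    thalidomide = "O=C1CCC(N2C(=O)c3ccccc3C2=O)C(=O)N1",
    imatinib = "Cc1ccc(NC(=O)c2ccc(CN3CCN(C)CC3)cc2)cc1Nc1nccc(n1)-c1cccnc1",
    gefitinib = "COc1cc2ncnc(Nc3ccc(F)c(Cl)c3)c2cc1OCCCN1CCOCC1",
    erlotinib = "COCCOc1cc2ncnc(Nc3cccc(C#C)c3)c2cc1OCCOC",
    sorafenib = "CNC(=O)c1cc(Oc2ccc(NC(=O)Nc3ccc(Cl)c(c3)C(F)(F)F)cc2)ccn1",
    lapatinib = "CS(=O)(=O)CCNCc1ccc(o1)-c1ccc2ncnc(Nc3ccc(OCc4cccc(F)c4)c(Cl)c3)c2c1",
    bosentan = "CC(C)(C)c1ccc(cc1)S(=O)(=O)Nc1ncnc(OCCO)c1Oc1ccccc1OC",
    ambrisentan = "COC(c1ccccc1)(c1ccccc1)C(Cc1nc(C)cc(C)n1)C(=O)O",
    troglitazone = "Cc1c(C)c2CCC(C)(COc3ccc(CC4SC(=O)NC4=O)cc3)Oc2c(C)c1O",
    rofecoxib = "O=C1OCC(=C1c1ccccc1)c1ccc(cc1)S(C)(=O)=O",
    nimesulide = "CS(=O)(=O)Nc1ccc(cc1Oc1ccccc1)[N+](=O)[O-]",
    ticlopidine = "Clc1ccccc1CN1CCc2sccc2C1",
    clopidogrel = "COC(=O)C(N1CCc2sccc2C1)c1ccccc1Cl",
    dipyridamole = "OCCN(CCO)c1nc2c(nc(nc2N2CCCCC2)N(CCO)CCO)c(n1)N1CCCCC1",
    cilostazol = "O=C1CCc2cc(OCCCCc3nnnn3C3CCCCC3)ccc2N1",
    pentoxifylline = "CC(=O)CCCCn1c(=O)n(C)c2nc[nH]c2c1=O",
    sibutramine = "CC(C)CC(N(C)C)C1(CCC1)c1ccc(Cl)cc1",
    orlistat = "CCCCCCCCCCCC(CC1OC(=O)C1CCCCCC)OC(=O)C(CC(C)C)NC=O",
    rimonabant = "Cc1c(nn(c1-c1ccc(Cl)cc1)-c1ccc(Cl)cc1Cl)C(=O)NN1CCCCC1",
    nicotine = "CN1CCCC1c1cccnc1",
    bupivacaine = "CCCCN1CCCCC1C(=O)Nc1c(C)cccc1C",
    lidocaine = "CCN(CC)CC(=O)Nc1c(C)cccc1C",
    procaine = "CCN(CC)CCOC(=O)c1ccc(N)cc1",
    benzocaine = "CCOC(=O)c1ccc(N)cc1",
    phenobarbital = "CCC1(c2ccccc2)C(=O)NC(=O)NC1=O",
    primidone = "CCC1(c2ccccc2)C(=O)NCNC1=O",
    topiramate = "CC1(C)OC2COC3(COS(N)(=O)=O)OC(C)(C)OC3C2O1",
    levetiracetam = "CCC(N1CCCC1=O)C(N)=O",
    vigabatrin = "NC(CCC(=O)O)C=C",
    amiodarone = "CCCCc1oc2ccccc2c1C(=O)c1cc(I)c(OCCN(CC)CC)c(I)c1",
    dronedarone = "CCCCc1oc2ccc(NS(C)(=O)=O)cc2c1C(=O)c1ccc(OCCCN(CCCC)CCCC)cc1",
    flecainide = "FC(F)(F)COc1ccc(OCC(F)(F)F)c(c1)C(=O)NCC1CCCCN1",
    propafenone = "CCCNCC(O)COc1ccccc1C(=O)CCc1ccccc1",
    sotalol = "CC(C)NCC(O)c1ccc(NS(C)(=O)=O)cc1",
    dofetilide = "CN(CCOc1ccc(NS(C)(=O)=O)cc1)CCc1ccc(NS(C)(=O)=O)cc1",
    ajmaline = "CCC1CC2CC3N(C)c4ccccc4C33CC(C1O)C2C3O"
  )
}
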