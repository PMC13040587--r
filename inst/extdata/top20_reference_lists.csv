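"comparison","modality","code"
"BD","GM","SFGdor.B"
"BD","GM","IFGoperc.R"
"BD","GM","ROL.R"
"BD","GM","SMA.L"
"BD","GM","OLF.L"
"BD","GM","SFGmed.L"
"BD","GM","ORBsupmed.B"
"BD","GM","REC.R"
"BD","GM","INS.L"
"BD","GM","HIP.L"
"BD","GM","AMYG.L"
"BD","GM","SPG.R"
"BD","GM","CAU.B"
"BD","GM","THA.B"
"BD","GM","HES.L"
"BD","GM","TPOsup.L"
"MDD","GM","SFGdor.L"
"MDD","GM","ORBsup.B"
"MDD","GM","ROL.R"
"MDD","GM","SMA.L"
"MDD","GM","OLF.L"
"MDD","GM","SFGmed.L"
"MDD","GM","ORBsupmed.B"
"MDD","GM","REC.B"
"MDD","GM","INS.B"
"MDD","GM","ACG.L"
"MDD","GM","CAU.R"
"MDD","GM","THA.R"
"MDD","GM","HES.B"
"MDD","GM","STG.L"
"MDD","GM","TPOsup.L"
"BD","FA","MCP"
"BD","FA","CC"
"BD","FA","FX"
"BD","FA","CST.B"
"BD","FA","ICP.R"
"BD","FA","ACR.R"
"BD","FA","SCR.L"
"BD","FA","PCR.B"
"BD","FA","PTR.B"
"BD","FA","SS.L"
"BD","FA","EC.L"
"BD","FA","FXST.B"
"BD","FA","TAP.B"
"MDD","FA","MCP"
"MDD","FA","CC"
"MDD","FA","FX"
"MDD","FA","CST.B"
"MDD","FA","ICP.R"
"MDD","FA","RLIC.B"
"MDD","FA","SCR.L"
"MDD","FA","PCR.B"
"MDD","FA","PTR.B"
"MDD","FA","SS.R"
"MDD","FA","EC.R"
"MDD","FA","FXST.R"
"MDD","FA","TAP.B"
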