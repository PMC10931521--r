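<?xml version="1.0" encoding="UTF-8"?>
<sbml xmlns="http://www.sbml.org/sbml/level3/version1/core" xmlns:fbc="http://www.sbml.org/sbml/level3/version1/fbc/version2" level="3" version="1" fbc:required="false">
  <model id="chain" fbc:strict="true">
    <listOfCompartments>
      <compartment id="c" name="cytosol" constant="true"/>
      <compartment id="e" name="extracellular" constant="true"/>
    </listOfCompartments>
    <listOfSpecies>
      <species id="M_A_e" name="A_e" compartment="e" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_A_c" name="A_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_B_c" name="B_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
      <species id="M_atp_c" name="atp_c" compartment="c" hasOnlySubstanceUnits="false" boundaryCondition="false" constant="false"/>
    </listOfSpecies>
    <listOfParameters>
      <parameter id="bnd_0" value="-10" constant="true"/>
      <parameter id="bnd_1" value="0" constant="true"/>
      <parameter id="bnd_2" value="1000" constant="true"/>
    </listOfParameters>
    <fbc:listOfObjectives fbc:activeObjective="obj">
      <fbc:objective fbc:id="obj" fbc:type="maximize">
        <fbc:listOfFluxObjectives>
          <fbc:fluxObjective fbc:reaction="R_DM_atp" fbc:coefficient="1"/>
        </fbc:listOfFluxObjectives>
      </fbc:objective>
    </fbc:listOfObjectives>
    <fbc:listOfGeneProducts>
      <fbc:geneProduct fbc:id="G_g_ab1" fbc:label="g_ab1"/>
      <fbc:geneProduct fbc:id="G_g_ab2" fbc:label="g_ab2"/>
      <fbc:geneProduct fbc:id="G_g_batp" fbc:label="g_batp"/>
      <fbc:geneProduct fbc:id="G_g_t" fbc:label="g_t"/>
    </fbc:listOfGeneProducts>
    <listOfReactions>
      <reaction id="R_EX_A_e" reversible="true" fast="false" fbc:lowerFluxBound="bnd_0" fbc:upperFluxBound="bnd_2">
        <listOfReactants>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
      <reaction id="R_T_A" reversible="false" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_2">
        <listOfReactants>
          <speciesReference species="M_A_e" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_t"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R_AB" reversible="false" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_2">
        <listOfReactants>
          <speciesReference species="M_A_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:and>
            <fbc:geneProductRef fbc:geneProduct="G_g_ab1"/>
            <fbc:geneProductRef fbc:geneProduct="G_g_ab2"/>
          </fbc:and>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_R_BATP" reversible="false" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_2">
        <listOfReactants>
          <speciesReference species="M_B_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
        <listOfProducts>
          <speciesReference species="M_atp_c" stoichiometry="1" constant="true"/>
        </listOfProducts>
        <fbc:geneProductAssociation>
          <fbc:geneProductRef fbc:geneProduct="G_g_batp"/>
        </fbc:geneProductAssociation>
      </reaction>
      <reaction id="R_DM_atp" reversible="false" fast="false" fbc:lowerFluxBound="bnd_1" fbc:upperFluxBound="bnd_2">
        <listOfReactants>
          <speciesReference species="M_atp_c" stoichiometry="1" constant="true"/>
        </listOfReactants>
      </reaction>
    </listOfReactions>
  </model>
</sbml>
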