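{
  "meta": {
    "fixture": "SYNTHETIC reconstruction of the pre-screening (round-1) framework",
    "note": "The pre-screening framework was never published; this stand-in is the final framework plus the three round-1-excluded indicators (placed under a 'Digital security' secondary) and the pre-revision names. Original wording of the excluded items beyond their names is not recoverable.",
    "counts": {
      "primary": 3,
      "secondary": 10,
      "tertiary": 22
    }
  },
  "indicators": [
    {
      "id": "1",
      "name": "Health problem solving",
      "interpretation": "Health literacy needed by the public when seeking help with health in digital environments: identifying health needs, making health decisions, and using decisions to promote health behavior change."
    },
    {
      "id": "1.1",
      "name": "Health needs expression competency",
      "interpretation": "Awareness of one's own health needs and the ability to accurately assess and express them in a data environment."
    },
    {
      "id": "1.1.1",
      "name": "Health problem assessment",
      "interpretation": "Accurately assess health problems when seeking health help in the digital environment."
    },
    {
      "id": "1.1.2",
      "name": "Health needs expression",
      "interpretation": "Accurately explain and express health information needs when seeking help with health in a digital environment."
    },
    {
      "id": "1.2",
      "name": "Health decision making competency",
      "interpretation": "Use digital tools and technologies to make sound health decisions based on acquired health data, information and knowledge."
    },
    {
      "id": "1.2.1",
      "name": "Personalized health decision making",
      "interpretation": "Use health information to make personalized health decisions when seeking health help in a digital environment."
    },
    {
      "id": "1.3",
      "name": "Health behavior change competency",
      "interpretation": "Use health decision-making to promote health behavior change."
    },
    {
      "id": "1.3.1",
      "name": "Adverse health behavior change",
      "interpretation": "Use personalized health decisions to change poor health behaviors."
    },
    {
      "id": "2",
      "name": "Information literacy",
      "interpretation": "Information literacy for the public seeking help with health in the digital environment: browsing, searching, evaluating and managing health information."
    },
    {
      "id": "2.1",
      "name": "Health information acquisition competency",
      "interpretation": "Search for health data, information and content in the digital environment, access them, and create and update personal search strategies."
    },
    {
      "id": "2.1.1",
      "name": "Search tool selection",
      "interpretation": "Choose appropriate search tools when seeking health help in digital environments."
    },
    {
      "id": "2.1.2",
      "name": "Search strategy construction",
      "interpretation": "Use appropriate search language and search form when seeking help for health in the digital environment."
    },
    {
      "id": "2.2",
      "name": "Health information screening competency",
      "interpretation": "Analyze, compare and critically assess the credibility and reliability of sources of health data, information and digital content."
    },
    {
      "id": "2.2.1",
      "name": "Health information screening",
      "interpretation": "Reason critically and evaluate information and data in the digital environment."
    },
    {
      "id": "2.2.2",
      "name": "Health information reasoning evaluation",
      "interpretation": "Assess the reliability and authority of health information content through information sources."
    },
    {
      "id": "2.2.3",
      "name": "Health information comparative evaluation",
      "interpretation": "Judge the correctness of information by comparing different information when seeking health help."
    },
    {
      "id": "2.3",
      "name": "Health information management competency",
      "interpretation": "Store and organize health data, information and content in a digital environment."
    },
    {
      "id": "2.3.1",
      "name": "Health information preservation/collection",
      "interpretation": "Save and collect health information in the digital environment."
    },
    {
      "id": "2.3.2",
      "name": "Health information organization",
      "interpretation": "Classify and organize health information in the digital environment."
    },
    {
      "id": "3",
      "name": "Emotion and communication",
      "interpretation": "Digital competency for the public seeking help with health in the digital environment: digital interaction, digital emotions, digital safety and digital health protection."
    },
    {
      "id": "3.1",
      "name": "Digital interaction competency",
      "interpretation": "Use digital tools and technologies for communication and interaction on health-related issues, and for co-construction of health resources and knowledge."
    },
    {
      "id": "3.1.1",
      "name": "Health activity participation",
      "interpretation": "Use public and private digital services to participate in community health activities online."
    },
    {
      "id": "3.1.2",
      "name": "Health data sharing",
      "interpretation": "Share health data, information and digital content with others using appropriate digital technologies."
    },
    {
      "id": "3.1.3",
      "name": "Health problem discussion",
      "interpretation": "Participate in discussions on health-related issues through digital and online platforms to support sound health decisions."
    },
    {
      "id": "3.2",
      "name": "Digital emotional competency",
      "interpretation": "Recognize, understand and manage one's own and others' emotions in a digital environment, with empathy and inclusiveness in health-related online interaction."
    },
    {
      "id": "3.2.1",
      "name": "Emotion recognition and expression",
      "interpretation": "Understand and recognize one's own and others' health needs, feelings and concerns online."
    },
    {
      "id": "3.2.2",
      "name": "Internet etiquette",
      "interpretation": "Adopt proper online etiquette and a sense of morality and acceptance of digital ethics when seeking health help online."
    },
    {
      "id": "3.3",
      "name": "Digital protection competency",
      "interpretation": "Protect one's own and others' personal information, digital media, and physical and mental health when seeking help for health online."
    },
    {
      "id": "3.3.1",
      "name": "Personal information protection",
      "interpretation": "Avoid intentional or unintentional theft of important personal information or data in transmission, storage and use."
    },
    {
      "id": "3.3.2",
      "name": "Digital media protection",
      "interpretation": "Recognize whether digital media are exposed to cyber threats (viruses, malware) and take proper security precautions."
    },
    {
      "id": "3.3.3",
      "name": "Physical and mental health protection",
      "interpretation": "Avoid risks in the digital environment (e.g. cyberbullying) and protect one's own mental health and that of others."
    },
    {
      "id": "3.4",
      "name": "Digital security",
      "interpretation": "Security-related digital competencies (removed during consultation)."
    },
    {
      "id": "3.4.1",
      "name": "Digital identity management",
      "interpretation": "Manage one's digital identity (excluded after round 1)."
    },
    {
      "id": "3.4.2",
      "name": "Digital protection",
      "interpretation": "Protect digital assets and data (excluded after round 1)."
    },
    {
      "id": "3.4.3",
      "name": "Digital participation",
      "interpretation": "Participate in digital civic activities (excluded after round 1)."
    }
  ]
}
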